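test_that("target trajectories are anchored, stationary, and reproducible", {
  # zero noise degenerates to the valence anchor
  flat_pos <- generate_target_trajectory(60, "positive", noise_sd = 0,
                                         seed = 1)
  flat_neg <- generate_target_trajectory(60, "negative", noise_sd = 0,
                                         seed = 1)
  expect_true(all(flat_pos$value == 6.5))
  expect_true(all(flat_neg$value == 3.5))
  expect_equal(nrow(flat_pos), 60)
  expect_equal(diff(flat_pos$t_s), rep(1, 59))

  # Monte-Carlo: lag-1 autocorrelation matches the AR coefficient
  ac1 <- vapply(1:200, function(i) {
    s <- generate_target_trajectory(120, "positive", ar_coef = 0.8,
                                    noise_sd = 0.5, seed = i)
    stats::acf(s$value, lag.max = 1, plot = FALSE)$acf[2]
  }, numeric(1))
  expect_lt(abs(mean(ac1) - 0.8), 0.15)

  # determinism
  a <- generate_target_trajectory(120, "negative", seed = 99)
  b <- generate_target_trajectory(120, "negative", seed = 99)
  expect_identical(a, b)

  expect_error(generate_target_trajectory(-5, "positive"), "duration_s")
  expect_error(generate_target_trajectory(60, "positive", ar_coef = 1),
               "stationary")
  expect_error(generate_target_trajectory(60, "positive",
                                          sample_rate_hz = 0),
               "sample_rate_hz")
})

test_that("perceiver streams are correlation-calibrated mixtures", {
  tgt <- generate_target_trajectory(120, "positive", seed = 5)

  # high-fidelity limit
  hi <- generate_perceiver_stream(tgt, target_r = 0.99, seed = 11)
  expect_gt(cor(hi$value, tgt$value), 0.9)

  # null calibration: mean correlation ~ 0 across replicates
  r0 <- vapply(1:500, function(i) {
    p <- generate_perceiver_stream(tgt, target_r = 0, seed = i)
    cor(p$value, tgt$value)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.05)

  # strong anticorrelation has the right sign in every replicate
  rneg <- vapply(1:100, function(i) {
    p <- generate_perceiver_stream(tgt, target_r = -0.9, seed = i)
    cor(p$value, tgt$value)
  }, numeric(1))
  expect_true(all(rneg < 0))

  expect_error(generate_perceiver_stream(tgt, target_r = 1), "target_r")
  expect_error(generate_perceiver_stream(tgt, target_r = 0.5, lag_s = 500),
               "longer than the clip")
})

test_that("binned-pipeline correlation calibration holds across target levels", {
  # generator-to-scorer calibration at a coarse grid (the acceptance suite
  # runs the full grid at higher replication)
  for (rho in c(-0.8, 0.4)) {
    rs <- vapply(1:150, function(i) {
      tgt <- generate_target_trajectory(120, "positive", seed = 7000 + i,
                                        clip_id = "C01")
      p <- generate_perceiver_stream(tgt, target_r = rho, seed = 9000 + i,
                                     rater_id = "P001")
      pb <- truncate_edges(bin_stream(p))
      tb <- truncate_edges(bin_stream(tgt))
      pair <- align_pair(pb, tb)
      cor(pair$perceiver, pair$target)
    }, numeric(1))
    expect_lt(abs(mean(rs) - rho), 0.05)
  }
})

test_that("cohorts conserve counts, honor the null spec, and validate inputs", {
  ds <- small_cohort()
  expect_s3_class(ds$participants, "tbl_df")
  expect_equal(nrow(ds$assignments), 4 * 4)
  # every assigned pair has a perceiver and a target stream
  streams <- dplyr::distinct(ds$streams, clip_id, rater_id, role)
  per_pair <- dplyr::inner_join(
    ds$assignments, dplyr::filter(streams, role == "perceiver"),
    by = c("perceiver_id" = "rater_id", "clip_id" = "clip_id"))
  expect_equal(nrow(per_pair), nrow(ds$assignments))
  expect_true(all(ds$assignments$clip_id %in%
                    streams$clip_id[streams$role == "target"]))
  # equal valence counts per perceiver
  val <- ds$assignments |>
    dplyr::left_join(ds$clips, by = "clip_id") |>
    dplyr::count(perceiver_id, valence)
  expect_true(all(val$n == 2))
  expect_identical(ds$seed, 42L)

  # null effect spec: every true correlation equals tanh(z_intercept)
  null_es <- effect_spec(z_intercept = 0.5, beta_valence = 0,
                         beta_condition = 0, beta_moderator = 0,
                         beta_interaction = 0, sd_perceiver = 0,
                         sd_residual = 0)
  ds0 <- generate_cohort(4, 4, default_clip_set(4), effects = null_es,
                         seed = 3, synthesize_streams = FALSE)
  expect_equal(ds0$assignments$r_true, rep(tanh(0.5), 16))

  expect_error(generate_cohort(4, 5, default_clip_set(4)), "even")
  # too few clips of one valence
  lopsided <- default_clip_set(4)[c(1, 3, 5, 7, 2), ]
  expect_error(generate_cohort(4, 8, lopsided), "each valence")

  # determinism at the dataset level
  ds2 <- small_cohort()
  expect_identical(ds$streams, ds2$streams)
  expect_identical(ds$participants, ds2$participants)
})

test_that("interaction truth shifts realized EA where the moderator is low", {
  # alcohol arm should track worse than placebo among below-mean moderator
  # scores when the deficit is concentrated at low moderator values
  es <- effect_spec(beta_condition = 0, beta_interaction = 0.3,
                    sd_perceiver = 0.2, sd_residual = 0.45)
  hits <- vapply(1:100, function(i) {
    ds <- generate_cohort(54, 16, effects = es, seed = 5000 + i,
                          synthesize_streams = FALSE)
    d <- ds$assignments |>
      dplyr::left_join(ds$participants, by = c("perceiver_id" = "participant_id"))
    low <- dplyr::filter(d, r_audit < 10.65)
    mean(low$r_true[low$condition == "alcohol"]) <
      mean(low$r_true[low$condition == "placebo"])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("questionnaire tables have the stated moments and exact totals", {
  q <- generate_questionnaires(1000, seed = 8)
  expect_equal(nrow(q), 1000)
  # law of large numbers on the configured r-AUDIT mean
  expect_lt(abs(mean(q$r_audit) - 10.65), 0.5)
  # items 1-8 sum exactly to the revised total, each within range
  items <- as.matrix(q[, sprintf("audit_%d", 1:8)])
  expect_equal(unname(rowSums(items)), q$r_audit)
  expect_true(all(items >= 0 & items <= 4))
  expect_true(all(q$audit_full == q$r_audit + q$audit_9 + q$audit_10))
  expect_identical(q$hazard_flag, q$r_audit >= 8)
  expect_true(all(q$urge_baseline >= 0 & q$urge_baseline <= 10))
  expect_true(all(q$peak_daily_drinks >= q$avg_daily_drinks))
  # determinism
  expect_identical(q, generate_questionnaires(1000, seed = 8))
  expect_error(generate_questionnaires(0), "positive")
})

test_that("AUDIT-drinks coupling is recovered across seeds", {
  pos <- vapply(1:100, function(i) {
    q <- generate_questionnaires(54, seed = 100 + i, drinks_cor = 0.7)
    cor(q$r_audit, q$avg_daily_drinks) > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})

test_that("vodka volume follows both dosing conventions and splits in two", {
  ml <- compute_vodka_volume(c(57, 100), convention = "ml_per_kg")
  expect_equal(ml$total_ml, c(85.12, 149.33), tolerance = 0.005)
  expect_equal(ml$glass_ml, ml$total_ml / 2)
  g <- compute_vodka_volume(57, convention = "g_per_kg")
  expect_equal(g$total_ml, 107.88, tolerance = 0.05)
  expect_error(compute_vodka_volume(-1), "positive")
  expect_error(compute_vodka_volume(70, abv = 0), "abv")
})

test_that("score-level generator matches its stated model", {
  ea <- simulate_ea_scores(54, 16, seed = 21)
  expect_equal(nrow(ea), 864)
  expect_equal(as.vector(table(ea$valence)), c(432L, 432L))
  expect_identical(ea, simulate_ea_scores(54, 16, seed = 21))
  # with no noise terms the z values are exactly the linear predictor
  es <- effect_spec(z_intercept = 0.4, beta_valence = 0.2,
                    beta_condition = 0, beta_moderator = 0,
                    beta_interaction = 0, sd_perceiver = 0, sd_residual = 0)
  ea0 <- simulate_ea_scores(10, 4, effects = es, seed = 2)
  expect_equal(sort(unique(round(ea0$z, 10))), c(0.4, 0.6))
})
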