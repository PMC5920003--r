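test_that("containment dfs reproduce the three canonical model shapes", {
  ea <- simulate_ea_scores(54, 16, seed = 101)
  ea$excluded <- FALSE

  m_cond <- fit_mixed_model(ea, ~condition)
  expect_equal(m_cond$f_tests$df_num, 1)
  expect_equal(m_cond$f_tests$df_den, 52)
  expect_equal(m_cond$f_tests$effect_type, "between")

  m_val <- fit_mixed_model(ea, ~valence)
  expect_equal(m_val$f_tests$df_den, 53)
  expect_equal(m_val$f_tests$effect_type, "within")

  m_sex <- fit_mixed_model(ea, ~target_sex)
  expect_equal(m_sex$f_tests$df_den, 53)

  m_mod <- fit_mixed_model(ea, ~condition, moderator = "r_audit")
  ix <- m_mod$f_tests[m_mod$f_tests$term == "condition:moderator_c", ]
  expect_equal(ix$df_den, 50)
  sl <- simple_slopes(m_mod)
  expect_equal(sl$df, c(50, 50))
})

test_that("model accessors expose tidy coefficient and summary tables", {
  ea <- simulate_ea_scores(20, 8, seed = 5)
  m <- fit_mixed_model(ea, ~condition, moderator = "r_audit")
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("condition:moderator_c" %in% tidy(m, "f_tests")$term |
                "conditionalcohol:moderator_c" %in% td$term)
  gl <- glance(m)
  expect_equal(gl$n_subjects, 20)
  expect_equal(gl$n_obs, 160)
  expect_type(gl$converged, "logical")
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("mixed-model fixed effects match OLS on balanced data", {
  ea <- simulate_ea_scores(30, 8, seed = 6)
  m <- fit_mixed_model(ea, ~valence)
  ols <- lm(z ~ valence, data = transform(ea, valence = factor(
    valence, levels = c("negative", "positive"))))
  expect_equal(m$fixed_effects$estimate, unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("singular random intercepts downgrade to OLS with a flag", {
  # no perceiver-level variance at all: the random intercept is singular
  es <- effect_spec(sd_perceiver = 0, sd_residual = 0.3)
  ea <- simulate_ea_scores(16, 6, effects = es, seed = 1)
  expect_message(m <- fit_mixed_model(ea, ~condition), "singular")
  expect_true(m$downgraded)
  expect_s3_class(m$fit, "lm")
  expect_equal(m$f_tests$df_den, 14)  # containment rule still applies
})

test_that("simple slopes recover the interaction pattern and police inputs", {
  # deficit at low moderator, none at high: negative low contrast whose
  # magnitude dominates the high contrast
  es <- effect_spec(beta_condition = -0.2, beta_interaction = 0.3)
  ea <- simulate_ea_scores(54, 16, effects = es, seed = 900)
  m <- fit_mixed_model(ea, ~condition, moderator = "r_audit")
  sl <- simple_slopes(m)
  expect_lt(sl$estimate[1], 0)
  expect_lt(abs(sl$estimate[2]), abs(sl$estimate[1]))
  expect_equal(sl$d, cohens_d_from_t(sl$t, sl$df))
  expect_s3_class(plot_simple_slopes(m), "ggplot")

  m0 <- fit_mixed_model(ea, ~condition)
  expect_error(simple_slopes(m0), class = "eapipe_invalid_request")

  ea$r_audit <- 10
  expect_error(suppressMessages(fit_mixed_model(ea, ~condition,
                                                moderator = "r_audit")),
               "zero variance")
})

test_that("generator betas are recovered without material bias", {
  es <- effect_spec(beta_condition = -0.1, beta_moderator = 0.05,
                    beta_interaction = 0.15)
  est <- t(vapply(1:150, function(i) {
    ea <- simulate_ea_scores(200, 16, effects = es, seed = 2000 + i)
    m <- fit_mixed_model(ea, ~condition, moderator = "r_audit")
    b <- m$fixed_effects$estimate
    names(b) <- m$fixed_effects$term
    b[c("conditionalcohol", "moderator_c", "conditionalcohol:moderator_c")]
  }, numeric(3)))
  # moderator slope is per raw r-AUDIT unit in the fit; truth is per SD
  bias <- colMeans(est) - c(-0.1, 0.05 / 3.9, 0.15 / 3.9)
  expect_true(all(abs(bias) < 0.05))
})

test_that("Cohen's d conversions reproduce printed effect sizes", {
  f_pairs <- tibble::tribble(
    ~f, ~df, ~d,
    17.86, 53, 1.16,
    0.82, 52, 0.25,
    0.02, 52, 0.04,
    1.53, 52, 0.34,
    0.29, 53, 0.15
  )
  expect_equal(round(cohens_d_from_f(f_pairs$f, f_pairs$df), 2), f_pairs$d)
  t_pairs <- tibble::tribble(
    ~t, ~df, ~d,
    -2.44, 50, 0.69,
    1.02, 50, 0.29,
    -2.55, 50, 0.72,
    0.72, 50, 0.20
  )
  expect_equal(round(cohens_d_from_t(t_pairs$t, t_pairs$df), 2), t_pairs$d)
  # the two conversions agree through F = t^2
  tt <- seq(0.1, 3, by = 0.3)
  expect_equal(cohens_d_from_f(tt^2, 50), cohens_d_from_t(tt, 50))
  expect_equal(cohens_d_from_f(0, 50), 0)
  expect_error(cohens_d_from_f(-1, 50), "nonnegative")
  expect_error(cohens_d_from_t(1, 0), "df")
})

test_that("summary-statistic t tests reproduce baseline-table rows", {
  age <- two_sample_t(24.54, 5.44, 26, 24.64, 7.32, 28)
  expect_equal(round(age$t, 2), -0.06)
  expect_equal(age$df, 52)
  # printed inputs are rounded to 2 dp, so allow 0.01 on the statistic
  sias <- two_sample_t(16.31, 9.78, 26, 15.43, 7.37, 28)
  expect_equal(sias$t, 0.37, tolerance = 0.011 / 0.37)
  urge <- two_sample_t(4.88, 2.47, 26, 4.89, 2.60, 28)
  expect_equal(round(urge$t, 2), -0.01)
  same <- two_sample_t(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)

  w <- two_sample_t(82.26, 18.10, 26, 78.68, 10.52, 28, method = "welch")
  expect_lt(w$df, 52)  # Satterthwaite df shrink under unequal variances
  expect_error(two_sample_t(1, 0, 5, 2, 0, 5),
               class = "eapipe_undefined_statistic")
})

test_that("one-sample t reproduces the breath-alcohol contrast", {
  bac <- one_sample_t(0.25, 0.06, 28)
  expect_equal(round(abs(bac$t)), 22)
  expect_equal(bac$df, 27)
  expect_equal(one_sample_t(3, 1.5, 10, mu0 = 3)$t, 0)
  hand <- one_sample_t(1, 1, 4)
  expect_equal(hand$t, 2)
  expect_equal(hand$df, 3)
  expect_error(one_sample_t(1, 0, 5), class = "eapipe_undefined_statistic")
})

test_that("Cronbach's alpha matches closed forms and null behavior", {
  x <- rnorm(100)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)

  set.seed(51)
  noise <- matrix(rnorm(10000 * 8), ncol = 8)
  expect_lt(abs(cronbach_alpha(noise)), 0.05)

  # two equal-variance items at sample correlation exactly 0.6:
  # Spearman-Brown gives 2*rho / (1 + rho) = 0.75
  n <- 400
  a <- scale(rnorm(n))[, 1]
  b <- scale(stats::residuals(lm(rnorm(n) ~ a)))[, 1]
  x2 <- 0.6 * a + 0.8 * b
  expect_equal(cronbach_alpha(cbind(a, x2)), 0.75, tolerance = 1e-10)

  expect_error(cronbach_alpha(matrix(1, 10, 3)),
               class = "eapipe_undefined_statistic")
  expect_error(cronbach_alpha(matrix(1, 10, 1)), "2 items")
})

test_that("AUDIT scoring applies the revised total and hazard cutoff", {
  expect_equal(score_audit(rep(0L, 10)), list(total = 0L,
                                              hazard_flag = FALSE))
  expect_equal(score_audit(c(rep(4L, 8), 0L, 0L)),
               list(total = 32L, hazard_flag = TRUE))
  r <- score_audit(c(rep(1L, 8), 4L, 4L))
  expect_equal(r$total, 8L)
  expect_true(r$hazard_flag)
  full <- score_audit(c(rep(1L, 8), 4L, 4L), revised = FALSE)
  expect_equal(full$total, 16L)
  expect_error(score_audit(c(rep(1L, 9), 5L)),
               class = "eapipe_invalid_input")
})

test_that("drinking summaries cover correlations, groups, and urge tests", {
  q <- generate_questionnaires(54, seed = 61)
  q$condition <- rep(c("alcohol", "placebo"), 27)
  ds <- drinking_summaries(q)
  expect_equal(nrow(ds$correlations), 2)
  expect_true(all(ds$correlations$r > 0))
  expect_equal(nrow(ds$urge_tests), 4)
  expect_true(all(c("t", "df", "p") %in% names(ds$urge_tests)))

  # perfectly proportional drinks give r = 1
  q2 <- q
  q2$avg_daily_drinks <- q2$r_audit * 0.4
  expect_equal(drinking_summaries(q2)$correlations$r[1], 1)
})
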