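#' Ground-truth effect structure for the synthetic cohort
#'
#' Bundles the fixed-effect and variance parameters (all on the Fisher-z
#' scale) that drive the generative model of empathic accuracy: per
#' perceiver-by-clip pair the true tracking correlation is
#' `tanh(z_intercept + beta_valence * I[positive] + beta_condition * I[alcohol]
#' + beta_moderator * m + beta_interaction * I[alcohol] * m + u_i + e_ij)`,
#' where `m` is the hazardous-drinking moderator standardized by its stated
#' mean and SD, `u_i` is a perceiver random intercept and `e_ij` a residual.
#'
#' Defaults are calibrated so that the true tracking correlations match a
#' typical moderate-dose alcohol-administration study: mean true r about 0.63
#' overall (0.67 positive, 0.59 negative clips), no moderator main effect,
#' and an alcohol deficit concentrated among low-moderator perceivers. Note
#' the sign logic of the interaction: the condition contrast at one moderator
#' SD below the mean is `beta_condition - beta_interaction`, at one SD above
#' `beta_condition + beta_interaction`, so a *positive* `beta_interaction`
#' with a negative `beta_condition` produces a deficit at low moderator
#' scores that vanishes at high scores.
#'
#' @param z_intercept Fisher-z intercept (expected z for a negative clip,
#'   placebo condition, moderator at its mean).
#' @param beta_valence Positive-minus-negative shift, Fisher-z units.
#' @param beta_condition Alcohol-minus-placebo shift, Fisher-z units.
#' @param beta_moderator Slope per moderator SD, Fisher-z units.
#' @param beta_interaction Condition-by-moderator slope per moderator SD.
#' @param sd_perceiver SD of the perceiver random intercept (>= 0).
#' @param sd_residual SD of the pair-level residual (>= 0).
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(z_intercept = 0.678,
                        beta_valence = 0.133,
                        beta_condition = -0.10,
                        beta_moderator = 0,
                        beta_interaction = 0.15,
                        sd_perceiver = 0.2,
                        sd_residual = 0.45) {
  assert_scalar_number(sd_perceiver, "sd_perceiver", lower = 0)
  assert_scalar_number(sd_residual, "sd_residual", lower = 0)
  for (nm in c("z_intercept", "beta_valence", "beta_condition",
               "beta_moderator", "beta_interaction")) {
    assert_scalar_number(get(nm), nm)
  }
  structure(
    list(z_intercept = z_intercept,
         beta_valence = beta_valence,
         beta_condition = beta_condition,
         beta_moderator = beta_moderator,
         beta_interaction = beta_interaction,
         sd_perceiver = sd_perceiver,
         sd_residual = sd_residual),
    class = "effect_spec"
  )
}

#' Default clip-set metadata
#'
#' Builds a clip set shaped like the validated stimulus sets used in
#' empathic-accuracy tasks: `n_targets` targets (half male, half female), each
#' contributing one positive and one negative clip of roughly two minutes.
#'
#' @param n_targets Number of distinct targets (even).
#' @param duration_s Clip duration in seconds (>= 30).
#' @return A tibble with columns `clip_id`, `target_id`, `target_sex`,
#'   `valence`, `duration_s`.
#' @export
default_clip_set <- function(n_targets = 10, duration_s = 120) {
  assert_scalar_number(duration_s, "duration_s", lower = 30)
  if (n_targets < 2 || n_targets %% 2 != 0) {
    abort("`n_targets` must be an even number >= 2.")
  }
  targets <- sprintf("T%02d", seq_len(n_targets))
  sexes <- rep(c("male", "female"), length.out = n_targets)
  tibble(
    clip_id = sprintf("C%02d", seq_len(2 * n_targets)),
    target_id = rep(targets, each = 2),
    target_sex = rep(sexes, each = 2),
    valence = rep(c("positive", "negative"), times = n_targets),
    duration_s = duration_s
  )
}

valence_anchor <- function(valence) {
  switch(valence, positive = 6.5, negative = 3.5,
         abort("`valence` must be 'positive' or 'negative'."))
}

#' Simulate a target's continuous affect-rating trajectory
#'
#' Generates a mean-reverting AR(1) dial trace around a valence-dependent
#' anchor (above the neutral midpoint 5 for positive clips, below it for
#' negative clips), hard-clipped to the 1-9 dial range, sampled at a fixed
#' rate.
#'
#' @param duration_s Clip duration in seconds (> 0).
#' @param valence `"positive"` or `"negative"`.
#' @param ar_coef AR(1) coefficient in `[0, 1)`.
#' @param noise_sd Innovation SD in dial units (>= 0). Zero gives a constant
#'   series at the anchor.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param seed Integer seed; identical seeds reproduce identical streams.
#' @param clip_id,rater_id Identifiers carried into the output.
#' @return A rating-stream tibble with columns `clip_id`, `rater_id`, `role`,
#'   `t_s`, `value`.
#' @export
generate_target_trajectory <- function(duration_s, valence,
                                       ar_coef = 0.8, noise_sd = 0.5,
                                       sample_rate_hz = 1, seed = NULL,
                                       clip_id = NA_character_,
                                       rater_id = "target") {
  assert_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!is.numeric(ar_coef) || ar_coef < 0 || ar_coef >= 1) {
    abort("`ar_coef` must lie in [0, 1): the process must be stationary.")
  }
  anchor <- valence_anchor(valence)
  n <- max(1L, as.integer(round(duration_s * sample_rate_hz)))
  x <- with_seed(seed, {
    if (noise_sd == 0) {
      rep(anchor, n)
    } else {
      stat_sd <- noise_sd / sqrt(1 - ar_coef^2)
      x0 <- rnorm(1, 0, stat_sd)
      eps <- rnorm(n, 0, noise_sd)
      dev <- as.numeric(stats::filter(eps, ar_coef, method = "recursive",
                                      init = x0))
      anchor + dev
    }
  })
  tibble(
    clip_id = clip_id,
    rater_id = rater_id,
    role = "target",
    t_s = (seq_len(n) - 1) / sample_rate_hz,
    value = pmin(9, pmax(1, x))
  )
}

#' Simulate a perceiver's rating stream tracking a target
#'
#' Builds the perceiver series as a correlation-calibrated mixture of the
#' (optionally lagged, standardized) target series and an independent AR(1)
#' noise series, so that the expected Pearson correlation with the target
#' equals `target_r`, then maps the result back onto the target's dial scale
#' and clips to `[1, 9]`. Clipping can shrink realized correlations slightly.
#'
#' @param target A rating-stream tibble (the target's trace for one clip).
#' @param target_r Desired expected correlation, strictly inside (-1, 1).
#' @param lag_s Perceiver response lag in seconds (>= 0, shorter than the
#'   clip).
#' @param noise_ar AR(1) coefficient of the noise series; defaults to the
#'   target's lag-1 sample autocorrelation so binning affects both components
#'   alike.
#' @param seed Integer seed.
#' @param rater_id Identifier for the perceiver.
#' @return A rating-stream tibble with `role = "perceiver"`.
#' @export
generate_perceiver_stream <- function(target, target_r, lag_s = 0,
                                      noise_ar = NULL, seed = NULL,
                                      rater_id = "perceiver") {
  require_columns(target, c("t_s", "value"), "`target`")
  if (nrow(target) == 0) abort("`target` stream is empty.")
  if (!is.numeric(target_r) || abs(target_r) >= 1) {
    abort("`target_r` must lie strictly inside (-1, 1).")
  }
  assert_scalar_number(lag_s, "lag_s", lower = 0)
  n <- nrow(target)
  dt <- if (n > 1) stats::median(diff(target$t_s)) else 1
  k <- as.integer(round(lag_s / dt))
  if (k >= n) abort("`lag_s` is longer than the clip.")
  tv <- target$value
  tlag <- tv[pmax(1L, seq_len(n) - k)]
  m <- mean(tlag)
  s <- sd(tlag)
  if (target_r != 0 && (!is.finite(s) || s == 0)) {
    abort("target series is constant; a nonzero tracking correlation is undefined.")
  }
  phi <- noise_ar %||% {
    if (n > 2 && s > 0) {
      a <- stats::acf(tv, lag.max = 1, plot = FALSE)$acf[2]
      min(max(a, 0), 0.95)
    } else 0.8
  }
  value <- with_seed(seed, {
    eps <- rnorm(n)
    noise <- as.numeric(stats::filter(eps * sqrt(1 - phi^2), phi,
                                      method = "recursive",
                                      init = rnorm(1)))
    nstd <- if (sd(noise) > 0) (noise - mean(noise)) / sd(noise) else noise
    if (s > 0) {
      tstd <- (tlag - m) / s
      mix <- target_r * tstd + sqrt(1 - target_r^2) * nstd
      m + s * mix
    } else {
      # constant target, target_r must be 0: independent noise on dial scale
      m + nstd
    }
  })
  tibble(
    clip_id = target$clip_id[1] %||% NA_character_,
    rater_id = rater_id,
    role = "perceiver",
    t_s = target$t_s,
    value = pmin(9, pmax(1, value))
  )
}

#' Simulate a full study cohort with known ground truth
#'
#' Generates everything downstream stages need: clip assignments in
#' constraint-respecting pseudo-random order, participant records with
#' questionnaire scores, target trajectories (one per clip, shared across
#' perceivers), and perceiver streams whose true tracking correlation follows
#' the generative model in [effect_spec()].
#'
#' Perceivers are assigned to conditions 1:1 alternating (alcohol first), so
#' arms differ by at most one participant. Each perceiver's moderator score is
#' the r-AUDIT total from the questionnaire generator, standardized by the
#' stated `moderator_mean`/`moderator_sd` when entering the linear predictor.
#'
#' @param n_perceivers Number of perceivers.
#' @param n_clips Clips per perceiver (even; half positive, half negative).
#' @param clip_set Clip metadata, e.g. [default_clip_set()].
#' @param effects An [effect_spec()].
#' @param moderator_mean,moderator_sd Stated moderator distribution (r-AUDIT
#'   score units); draws are truncated to the instrument range `[0, 32]`.
#' @param seed Integer seed.
#' @param sample_rate_hz Dial sampling rate in Hz.
#' @param ar_coef,noise_sd Target-trajectory AR(1) parameters.
#' @param synthesize_streams Generate the rating streams (default). Set to
#'   FALSE for design-level simulations that only need assignments and the
#'   realized true tracking correlations; the seed stream is unaffected, so
#'   assignments match a full run with the same seed.
#' @return A list of class `study_dataset` with elements `streams`, `clips`,
#'   `participants`, `assignments`, `truth`, `seed`.
#' @export
generate_cohort <- function(n_perceivers = 54, n_clips = 16,
                            clip_set = default_clip_set(),
                            effects = effect_spec(),
                            moderator_mean = 10.65, moderator_sd = 3.90,
                            seed = 1, sample_rate_hz = 1,
                            ar_coef = 0.8, noise_sd = 0.5,
                            synthesize_streams = TRUE) {
  if (n_clips %% 2 != 0) {
    abort("`n_clips` must be even: equal positive and negative counts.")
  }
  n_half <- n_clips / 2
  pos <- dplyr::filter(clip_set, .data$valence == "positive")
  neg <- dplyr::filter(clip_set, .data$valence == "negative")
  if (nrow(pos) < n_half || nrow(neg) < n_half) {
    abort("`clip_set` must hold at least n_clips/2 clips of each valence.")
  }
  stopifnot(inherits(effects, "effect_spec"))

  participants <- generate_questionnaires(
    n_perceivers, seed = child_seed(seed, 1),
    audit_mean = moderator_mean, audit_sd = moderator_sd
  )
  participants$condition <- rep(c("alcohol", "placebo"),
                                length.out = n_perceivers)
  participants <- add_bac_readings(participants, seed = child_seed(seed, 2))

  m_std <- (participants$r_audit - moderator_mean) / moderator_sd
  u <- with_seed(child_seed(seed, 3),
                 rnorm(n_perceivers, 0, effects$sd_perceiver))

  # one shared target stream per clip
  target_streams <- NULL
  if (synthesize_streams) {
    target_streams <- purrr::pmap(clip_set, function(clip_id, target_id,
                                                     target_sex, valence,
                                                     duration_s) {
      generate_target_trajectory(
        duration_s, valence, ar_coef = ar_coef, noise_sd = noise_sd,
        sample_rate_hz = sample_rate_hz,
        seed = child_seed(seed, 100 + match(clip_id, clip_set$clip_id)),
        clip_id = clip_id, rater_id = target_id
      )
    })
    names(target_streams) <- clip_set$clip_id
  }

  assignments <- vector("list", n_perceivers)
  perceiver_streams <- vector("list", n_perceivers)
  for (i in seq_len(n_perceivers)) {
    pid <- sprintf("P%03d", i)
    sel <- with_seed(child_seed(seed, 200 + i), {
      dplyr::bind_rows(
        pos[sample(nrow(pos), n_half), ],
        neg[sample(nrow(neg), n_half), ]
      )
    })
    ordered <- sample_clip_order(sel, seed = child_seed(seed, 300 + i))
    is_alc <- participants$condition[i] == "alcohol"
    eps <- with_seed(child_seed(seed, 400 + i),
                     rnorm(n_clips, 0, effects$sd_residual))
    z_true <- effects$z_intercept +
      effects$beta_valence * (ordered$valence == "positive") +
      effects$beta_condition * is_alc +
      effects$beta_moderator * m_std[i] +
      effects$beta_interaction * is_alc * m_std[i] +
      u[i] + eps
    r_true <- tanh(z_true)
    r_true <- pmin(0.99, pmax(-0.99, r_true))
    assignments[[i]] <- tibble(
      perceiver_id = pid,
      clip_id = ordered$clip_id,
      position = seq_len(n_clips),
      z_true = z_true,
      r_true = r_true
    )
    if (synthesize_streams) {
      perceiver_streams[[i]] <- purrr::map2(
        ordered$clip_id, seq_len(n_clips),
        function(cid, j) {
          generate_perceiver_stream(
            target_streams[[cid]], target_r = r_true[j],
            seed = child_seed(seed, 1000L + i * 101L + j),
            rater_id = pid
          )
        }
      ) |> list_rbind()
    }
  }

  streams <- if (synthesize_streams) {
    bind_rows(list_rbind(target_streams |> unname()),
              list_rbind(perceiver_streams))
  } else {
    tibble(clip_id = character(), rater_id = character(),
           role = character(), t_s = numeric(), value = numeric())
  }
  structure(
    list(
      streams = streams,
      clips = as_tibble(clip_set),
      participants = participants,
      assignments = list_rbind(assignments),
      truth = effects,
      seed = as.integer(seed)
    ),
    class = "study_dataset"
  )
}

# Gaussian rise-fall BAC profile at 10-min readings; zero in the placebo arm.
add_bac_readings <- function(participants, seed = NULL) {
  n <- nrow(participants)
  t_grid <- seq(0, 60, by = 10)
  with_seed(seed, {
    peak <- pmax(0.05, rnorm(n, 0.25, 0.06))
    tpeak <- pmax(10, pmin(50, rnorm(n, 21, 12)))
    alc <- participants$condition == "alcohol"
    bac <- sapply(seq_len(n), function(i) {
      if (!alc[i]) return(rep(0, length(t_grid)))
      prof <- peak[i] * exp(-((t_grid - tpeak[i]) / 30)^2)
      prof[1] <- 0  # sober at baseline
      round(prof, 3)
    })
    bac <- t(bac)
    colnames(bac) <- sprintf("bac_%d", t_grid)
    out <- bind_cols(participants, as_tibble(bac))
    out$bac_peak <- ifelse(alc, round(peak, 3), 0)
    out
  })
}

#' Simulate a participant questionnaire table
#'
#' Draws per-participant AUDIT item responses (items 9 and 10 are generated
#' but flagged unusable and excluded from the revised total), DMQ-R subscale
#' scores, SIAS total, four urge-to-drink ratings on the 0-10 scale, daily
#' drink counts coupled to the AUDIT latent at `drinks_cor`, an SMAST
#' inclusion flag, and body weight. Distribution defaults reflect a young
#' male social-drinker sample.
#'
#' @param n Number of participants (> 0).
#' @param seed Integer seed.
#' @param audit_mean,audit_sd Mean and SD of the r-AUDIT total (items 1-8,
#'   truncated to `[0, 32]`).
#' @param drinks_cor Latent correlation between the AUDIT total and the daily
#'   drink counts.
#' @return A tibble with one row per participant.
#' @export
generate_questionnaires <- function(n, seed = NULL,
                                    audit_mean = 10.65, audit_sd = 3.90,
                                    drinks_cor = 0.7) {
  if (!is.numeric(n) || n < 1) abort("`n` must be a positive count.")
  n <- as.integer(n)
  with_seed(seed, {
    latent <- rnorm(n)
    total <- round(audit_mean + audit_sd * latent)
    total <- pmin(32L, pmax(0L, as.integer(total)))
    items <- t(vapply(total, allocate_audit_items, integer(8)))
    colnames(items) <- sprintf("audit_%d", 1:8)
    extra <- matrix(sample(0:4, 2 * n, replace = TRUE), ncol = 2,
                    dimnames = list(NULL, c("audit_9", "audit_10")))
    mix <- function(rho, sd_y, mu_y) {
      mu_y + sd_y * (rho * latent + sqrt(1 - rho^2) * rnorm(n))
    }
    avg_drinks <- pmax(0.5, round(mix(drinks_cor, 1.3, 4.25), 1))
    peak_drinks <- pmax(avg_drinks, round(mix(drinks_cor, 3.9, 8.2), 1))
    urge <- function(mu, s) pmin(10, pmax(0, round(rnorm(n, mu, s))))
    out <- tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      weight_kg = round(pmin(130, pmax(55, rnorm(n, 80.4, 14.5))), 1),
      r_audit = rowSums(items),
      audit_full = rowSums(items) + rowSums(extra),
      hazard_flag = rowSums(items) >= 8,
      dmq_social = round(pmin(28, pmax(5, rnorm(n, 16.0, 4.3)))),
      dmq_enhancement = round(pmin(25, pmax(5, rnorm(n, 14.1, 4.6)))),
      dmq_coping = round(pmin(25, pmax(5, rnorm(n, 7.5, 2.5)))),
      dmq_conformity = round(pmin(25, pmax(5, rnorm(n, 6.3, 2.0)))),
      sias = round(pmin(76, pmax(0, rnorm(n, 15.8, 8.5)))),
      urge_baseline = urge(4.9, 2.5),
      urge_pre_drink = urge(4.9, 2.4),
      urge_post_drink = urge(4.7, 2.4),
      urge_post_task = urge(5.5, 2.2),
      avg_daily_drinks = avg_drinks,
      peak_daily_drinks = peak_drinks,
      smast = sample(0:2, n, replace = TRUE),
      smast_flag = TRUE
    )
    bind_cols(out[, 1:2], as_tibble(items), as_tibble(extra),
              out[, -(1:2)])
  })
}

# Distribute an integer total T in [0, 32] across 8 items, each in 0..4,
# exactly summing to T; random transfers decorrelate items while keeping the
# total fixed.
allocate_audit_items <- function(total) {
  base <- total %/% 8L
  rem <- total %% 8L
  items <- rep(as.integer(base), 8)
  if (rem > 0) {
    bump <- sample(8, rem)
    items[bump] <- items[bump] + 1L
  }
  for (k in seq_len(8)) {
    from <- sample(8, 1)
    to <- sample(8, 1)
    if (items[from] > 0 && items[to] < 4 && from != to) {
      items[from] <- items[from] - 1L
      items[to] <- items[to] + 1L
    }
  }
  items
}

#' Simulate Fisher-z EA scores directly from the generative model
#'
#' Draws the score-level quantities the inference module consumes (one
#' Fisher-z empathic-accuracy value per perceiver-by-clip pair) straight from
#' the linear mixed model implied by an [effect_spec()], skipping stream
#' synthesis. This is the generator used for large calibration simulations
#' (type-I error, parameter recovery) where thousands of replicates of the
#' full 54 x 16 design are needed; the stream-level round trip is exercised
#' separately.
#'
#' @inheritParams generate_cohort
#' @return A tibble with columns `perceiver_id`, `condition`, `r_audit`,
#'   `clip_id`, `valence`, `target_sex`, `z`, `r`.
#' @export
simulate_ea_scores <- function(n_perceivers = 54, n_clips = 16,
                               effects = effect_spec(),
                               moderator_mean = 10.65, moderator_sd = 3.90,
                               seed = NULL) {
  if (n_clips %% 2 != 0) abort("`n_clips` must be even.")
  with_seed(seed, {
    condition <- rep(c("alcohol", "placebo"), length.out = n_perceivers)
    m <- pmin(32, pmax(0, rnorm(n_perceivers, moderator_mean, moderator_sd)))
    m_std <- (m - moderator_mean) / moderator_sd
    u <- rnorm(n_perceivers, 0, effects$sd_perceiver)
    valence <- rep(c("positive", "negative"), each = n_clips / 2)
    target_sex <- rep(c("male", "female"), length.out = n_clips)
    grid <- tidyr::expand_grid(
      i = seq_len(n_perceivers),
      j = seq_len(n_clips)
    )
    is_alc <- condition[grid$i] == "alcohol"
    is_pos <- valence[grid$j] == "positive"
    z <- effects$z_intercept +
      effects$beta_valence * is_pos +
      effects$beta_condition * is_alc +
      effects$beta_moderator * m_std[grid$i] +
      effects$beta_interaction * is_alc * m_std[grid$i] +
      u[grid$i] +
      rnorm(nrow(grid), 0, effects$sd_residual)
    tibble(
      perceiver_id = sprintf("P%03d", grid$i),
      condition = condition[grid$i],
      r_audit = m[grid$i],
      clip_id = sprintf("C%02d", grid$j),
      valence = valence[grid$j],
      target_sex = target_sex[grid$j],
      z = z,
      r = tanh(z)
    )
  })
}
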