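#' Fit a random-intercept mixed model on Fisher-z EA scores
#'
#' Fits `z ~ fixed + (1 | subject)` by REML (via [lme4::lmer()]) and reports
#' Wald F tests for each fixed-effect term with containment (between-within)
#' denominator degrees of freedom: a between-subject effect (constant within
#' each subject) gets `n_subjects - p_between`, where `p_between` counts all
#' between-subject fixed-effect parameters including the intercept, while a
#' within-subject effect gets `n_subjects - 1`. With 54 subjects this yields
#' df (1, 52) for a condition-only model, (1, 53) for a within-subject factor
#' such as clip valence, and contrast df 50 for a
#' condition-by-moderator model. Single-df F tests carry Cohen's d via
#' [cohens_d_from_f()].
#'
#' When `moderator` is supplied it is grand-mean centered (over subject-level
#' scores) by default and crossed with the first term of `fixed` (the focal
#' predictor), matching the usual moderation layout
#' `z ~ condition * moderator_c (+ covariates)`.
#'
#' A singular random-intercept variance is downgraded to an ordinary linear
#' model with a message; non-convergence is flagged on the result, never
#' silently ignored.
#'
#' @param data EA table joined with participant covariates; rows flagged
#'   `excluded` are dropped. Character `condition` and `valence` columns are
#'   coerced to factors with reference levels `"placebo"` and `"negative"`.
#' @param fixed One-sided formula of fixed effects, e.g. `~ condition`.
#' @param moderator Optional column name of a continuous subject-level
#'   moderator.
#' @param center Grand-mean center the moderator (default TRUE).
#' @param subject Subject identifier column (default `"perceiver_id"`).
#' @param response Response column (default `"z"`).
#' @return An object of class `ea_model`.
#' @export
fit_mixed_model <- function(data, fixed = ~condition, moderator = NULL,
                            center = TRUE, subject = "perceiver_id",
                            response = "z") {
  require_columns(data, c(subject, response), "`data`")
  if ("excluded" %in% names(data)) {
    data <- dplyr::filter(data, !.data$excluded)
  }
  data <- dplyr::filter(data, is.finite(.data[[response]]))
  if ("condition" %in% names(data) && is.character(data$condition)) {
    lev <- unique(data$condition)
    lev <- c(intersect("placebo", lev), setdiff(sort(lev), "placebo"))
    data$condition <- factor(data$condition, levels = lev)
  }
  if ("valence" %in% names(data) && is.character(data$valence)) {
    data$valence <- factor(data$valence,
                           levels = intersect(c("negative", "positive"),
                                              unique(data$valence)))
  }

  fixed_terms <- attr(terms(fixed), "term.labels")
  mod_info <- NULL
  if (!is.null(moderator)) {
    require_columns(data, moderator, "`data`")
    if (length(fixed_terms) < 1) {
      abort("`fixed` must name a focal predictor to cross with the moderator.")
    }
    subj_scores <- data |>
      distinct(.data[[subject]], .data[[moderator]]) |>
      pull(moderator)
    mod_mean <- if (center) mean(subj_scores) else 0
    mod_sd <- sd(subj_scores)
    if (!is.finite(mod_sd) || mod_sd == 0) {
      abort("moderator has zero variance across subjects: moderation analysis is degenerate.")
    }
    data$moderator_c <- data[[moderator]] - mod_mean
    focal <- fixed_terms[1]
    extras <- fixed_terms[-1]
    rhs <- paste(c(sprintf("%s * moderator_c", focal), extras),
                 collapse = " + ")
    mod_info <- list(name = moderator, mean = mod_mean, sd = mod_sd,
                     focal = focal)
  } else {
    rhs <- paste(fixed_terms, collapse = " + ")
  }
  n_subjects <- dplyr::n_distinct(data[[subject]])
  if (!is.null(moderator) || "condition" %in% all.vars(fixed)) {
    if ("condition" %in% names(data)) {
      per_cond <- data |> distinct(.data[[subject]], .data$condition) |>
        count(.data$condition)
      if (any(per_cond$n < 2)) {
        abort("need at least 2 subjects per condition.")
      }
    }
  }

  full_formula <- as.formula(
    sprintf("%s ~ %s + (1 | %s)", response, rhs, subject))
  fit <- lme4::lmer(full_formula, data = data, REML = TRUE)
  singular <- lme4::isSingular(fit)
  converged <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0
  downgraded <- FALSE
  if (singular) {
    inform("random-intercept variance is singular; refitting as ordinary least squares.")
    fit <- lm(as.formula(sprintf("%s ~ %s", response, rhs)), data = data)
    downgraded <- TRUE
    converged <- TRUE
  }

  b <- if (downgraded) coef(fit) else lme4::fixef(fit)
  b <- b[!is.na(b)]  # lm drops aliased coefficients with NA
  V <- as.matrix(vcov(fit))
  mm <- model.matrix(as.formula(sprintf("~ %s", rhs)), data = data)
  term_labels <- attr(terms(as.formula(sprintf("~ %s", rhs))), "term.labels")
  # align the design to the estimated coefficients (rank-deficient fits drop
  # columns)
  keep <- match(names(b), colnames(mm))
  asg <- attr(mm, "assign")[keep]
  mm <- mm[, keep, drop = FALSE]

  # classify terms: between-subject iff every design column is constant
  # within every subject
  subj <- data[[subject]]
  col_between <- vapply(seq_len(ncol(mm)), function(j) {
    all(tapply(mm[, j], subj, function(v) max(v) - min(v)) == 0)
  }, logical(1))
  term_between <- vapply(seq_along(term_labels), function(k) {
    all(col_between[asg == k])
  }, logical(1))
  p_between <- 1L + sum(asg > 0 & col_between[seq_along(asg)])
  df_between <- n_subjects - p_between
  df_within <- n_subjects - 1L

  f_tests <- purrr::map(seq_along(term_labels), function(k) {
    idx <- which(asg == k)
    if (length(idx) == 0) return(NULL)  # term fully aliased out
    bk <- b[idx]
    Vk <- V[idx, idx, drop = FALSE]
    q <- length(idx)
    Fstat <- as.numeric(t(bk) %*% solve(Vk, bk)) / q
    df_den <- if (term_between[k]) df_between else df_within
    tibble(
      term = term_labels[k],
      f = Fstat,
      df_num = q,
      df_den = df_den,
      p = pf(Fstat, q, df_den, lower.tail = FALSE),
      d = if (q == 1) cohens_d_from_f(Fstat, df_den) else NA_real_,
      effect_type = if (term_between[k]) "between" else "within"
    )
  }) |> list_rbind()

  fixed_effects <- tibble(
    term = names(b),
    estimate = unname(b),
    std.error = sqrt(diag(V)),
    statistic = unname(b) / sqrt(diag(V))
  )

  structure(
    list(
      fit = fit,
      formula = full_formula,
      data = data,
      subject = subject,
      response = response,
      fixed_effects = fixed_effects,
      f_tests = f_tests,
      moderator = mod_info,
      n_subjects = n_subjects,
      n_obs = nrow(data),
      df_between = df_between,
      df_within = df_within,
      converged = converged,
      singular = singular,
      downgraded = downgraded
    ),
    class = "ea_model"
  )
}

#' Simple slopes of the focal effect at +/- 1 SD of the moderator
#'
#' Evaluates the focal contrast (e.g. alcohol minus placebo) at moderator
#' levels one SD below and one SD above the sample mean, using the model's
#' coefficient covariance and containment degrees of freedom; Cohen's d via
#' [cohens_d_from_t()].
#'
#' @param model An `ea_model` fitted with a moderator.
#' @param sd_multipliers Moderator levels in SD units around the mean
#'   (default `c(-1, 1)`).
#' @return A tibble with one row per level: `level`, `moderator_value`,
#'   `estimate`, `std.error`, `t`, `df`, `p`, `d`.
#' @export
simple_slopes <- function(model, sd_multipliers = c(-1, 1)) {
  stopifnot(inherits(model, "ea_model"))
  mi <- model$moderator
  if (is.null(mi)) {
    abort("model has no condition-by-moderator interaction.",
          class = "eapipe_invalid_request")
  }
  if (!is.finite(mi$sd) || mi$sd == 0) {
    abort("moderator SD is zero: +/- 1 SD levels are degenerate.")
  }
  b <- model$fixed_effects$estimate
  names(b) <- model$fixed_effects$term
  V <- as.matrix(vcov(model$fit))
  cn <- names(b)
  # focal main-effect coefficient: belongs to the focal term, not the
  # interaction; interaction coefficient contains both names
  is_int <- grepl(":", cn, fixed = TRUE) &
    grepl("moderator_c", cn, fixed = TRUE)
  focal_stub <- mi$focal
  is_focal <- startsWith(cn, focal_stub) & !grepl(":", cn, fixed = TRUE)
  if (sum(is_focal) != 1 || sum(is_int) != 1) {
    abort("could not identify a single focal and interaction coefficient.",
          class = "eapipe_invalid_request")
  }
  jf <- which(is_focal)
  ji <- which(is_int)
  purrr::map(sd_multipliers, function(mult) {
    lev_c <- mult * mi$sd
    est <- b[jf] + lev_c * b[ji]
    se <- sqrt(V[jf, jf] + lev_c^2 * V[ji, ji] + 2 * lev_c * V[jf, ji])
    tstat <- est / se
    df <- model$df_between
    tibble(
      level = sprintf("mean %s %g SD", ifelse(mult < 0, "-", "+"),
                      abs(mult)),
      moderator_value = mi$mean + lev_c,
      estimate = unname(est),
      std.error = unname(se),
      t = unname(tstat),
      df = df,
      p = 2 * pt(-abs(unname(tstat)), df),
      d = cohens_d_from_t(unname(tstat), df)
    )
  }) |> list_rbind()
}

#' @export
print.ea_model <- function(x, ...) {
  cat("Empathic-accuracy mixed model",
      if (x$downgraded) "(downgraded to OLS: singular random intercept)",
      "\n")
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  cat("  Fixed-effect F tests (containment df):\n")
  ft <- x$f_tests
  for (i in seq_len(nrow(ft))) {
    cat(sprintf("    %-28s F(%d,%d) = %6.2f, p = %.4g%s\n",
                ft$term[i], ft$df_num[i], ft$df_den[i], ft$f[i], ft$p[i],
                ifelse(is.na(ft$d[i]), "",
                       sprintf(", d = %.2f", ft$d[i]))))
  }
  invisible(x)
}

#' @describeIn fit_mixed_model Broom-style coefficient table; set
#'   `effects = "f_tests"` for the per-term F table.
#' @param x An `ea_model`.
#' @param effects `"fixed"` (coefficients) or `"f_tests"`.
#' @param ... Unused.
#' @method tidy ea_model
#' @export
tidy.ea_model <- function(x, effects = c("fixed", "f_tests"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$fixed_effects else x$f_tests
}

#' @describeIn fit_mixed_model One-row model summary.
#' @method glance ea_model
#' @export
glance.ea_model <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    df_between = x$df_between,
    df_within = x$df_within,
    converged = x$converged,
    singular = x$singular,
    downgraded = x$downgraded
  )
}
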