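#' Two-sample t test from summary statistics
#'
#' Computes the independent-samples t statistic from group means, SDs and
#' sizes, as needed to reproduce baseline-comparison tables that print only
#' summaries. `pooled` (default) is the classical Student test with
#' `df = n1 + n2 - 2`; `welch` uses the Welch statistic with Satterthwaite
#' df.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param method `"pooled"` or `"welch"`.
#' @return A tibble with columns `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2.")
  if (sd1 < 0 || sd2 < 0) abort("SDs must be nonnegative.")
  if (sd1 == 0 && sd2 == 0) {
    abort("both SDs are zero: t statistic undefined.",
          class = "eapipe_undefined_statistic")
  }
  if (method == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' One-sample t test from summary statistics
#'
#' @param mean,sd,n Sample summary statistics (`n >= 2`, `sd > 0`).
#' @param mu0 Null value.
#' @return A tibble with columns `t`, `df`, `p` (two-sided).
#' @export
one_sample_t <- function(mean, sd, n, mu0 = 0) {
  if (n < 2) abort("need n >= 2.")
  if (sd <= 0) {
    abort("zero SD: t statistic undefined.",
          class = "eapipe_undefined_statistic")
  }
  t <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cronbach's alpha for a set of questionnaire items
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))` with
#' `n - 1` denominators. Rows with missing values are dropped with a message.
#'
#' @param item_matrix Numeric matrix or data frame, respondents in rows,
#'   items (k >= 2) in columns.
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) abort("need at least 2 items.")
  cc <- complete.cases(m)
  if (!all(cc)) {
    inform(sprintf("dropping %d row(s) with missing values.", sum(!cc)))
    m <- m[cc, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least 2 complete respondents.")
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    abort("zero total-score variance: alpha undefined.",
          class = "eapipe_undefined_statistic")
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Score the AUDIT questionnaire
#'
#' The revised total (default) sums items 1-8 only (range 0-32), for use when
#' items 9 and 10 are unusable; the full total sums all 10 items (0-40). The
#' hazardous-drinking flag applies the standard cutoff of 8 to the computed
#' total.
#'
#' @param items Integer vector of 10 item responses, each in 0..4.
#' @param revised Use the items-1-to-8 total (default TRUE).
#' @param cutoff Hazard cutoff applied to the total.
#' @return A list with `total` and `hazard_flag`.
#' @export
score_audit <- function(items, revised = TRUE, cutoff = 8) {
  if (length(items) != 10 || any(is.na(items)) ||
      any(items != round(items)) || any(items < 0 | items > 4)) {
    abort("`items` must be 10 integers in 0..4.",
          class = "eapipe_invalid_input")
  }
  total <- if (revised) sum(items[1:8]) else sum(items)
  list(total = as.integer(total), hazard_flag = total >= cutoff)
}

#' Drinking and baseline descriptives for a participant table
#'
#' Produces the standard baseline-comparison surface: Pearson correlations of
#' the r-AUDIT total with average and peak daily drinks, per-condition
#' means/SDs of the baseline variables, and pooled two-sample t tests of the
#' four urge-to-drink ratings between conditions.
#'
#' @param participants Participant tibble with `condition`, `r_audit`,
#'   `avg_daily_drinks`, `peak_daily_drinks` and the urge columns.
#' @param t_method Passed to [two_sample_t()].
#' @return A list of tibbles: `correlations`, `group_summary`, `urge_tests`.
#' @export
drinking_summaries <- function(participants, t_method = "pooled") {
  require_columns(participants,
                  c("condition", "r_audit", "avg_daily_drinks",
                    "peak_daily_drinks"), "`participants`")
  if (nrow(participants) < 3) abort("need at least 3 participants.")
  cor_row <- function(yname) {
    y <- participants[[yname]]
    if (sd(participants$r_audit) == 0 || sd(y) == 0) {
      warn(sprintf("constant column: correlation with %s undefined.", yname))
      return(tibble(variable = yname, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(participants$r_audit, y)
    tibble(variable = yname, r = unname(ct$estimate), p = ct$p.value)
  }
  correlations <- bind_rows(cor_row("avg_daily_drinks"),
                            cor_row("peak_daily_drinks"))

  numeric_cols <- intersect(
    c("weight_kg", "r_audit", "sias", "dmq_social", "dmq_enhancement",
      "dmq_coping", "dmq_conformity", "avg_daily_drinks",
      "peak_daily_drinks", "urge_baseline", "urge_pre_drink",
      "urge_post_drink", "urge_post_task"),
    names(participants))
  group_summary <- participants |>
    tidyr::pivot_longer(all_of(numeric_cols), names_to = "variable") |>
    group_by(.data$condition, .data$variable) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = sd(.data$value), .groups = "drop")

  urge_cols <- intersect(c("urge_baseline", "urge_pre_drink",
                           "urge_post_drink", "urge_post_task"),
                         names(participants))
  urge_tests <- purrr::map(urge_cols, function(col) {
    s <- group_summary |>
      dplyr::filter(.data$variable == col) |>
      arrange(.data$condition)  # alcohol first, then placebo
    alc <- s[s$condition == "alcohol", ]
    plc <- s[s$condition == "placebo", ]
    tt <- two_sample_t(plc$mean, plc$sd, plc$n, alc$mean, alc$sd, alc$n,
                       method = t_method)
    bind_cols(tibble(timepoint = col), tt)
  }) |> list_rbind()

  list(correlations = correlations, group_summary = group_summary,
       urge_tests = urge_tests)
}
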