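#' Fisher z transformation of a correlation
#'
#' `z = atanh(r)`, with `|r|` clipped at `clip_at` first so that perfect
#' correlations (which real binned dial data do produce) map to a finite z
#' rather than infinity. [inverse_fisher_z()] is `tanh` and inverts the
#' transform exactly for `|r| < clip_at`.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param clip_at Magnitude at which `|r|` is clipped before `atanh`.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r, clip_at = 0.999) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    abort("`r` must lie in [-1, 1].")
  }
  atanh(sign(r) * pmin(abs(r), clip_at))
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Per-clip empathic-accuracy correlation
#'
#' Correlates an aligned perceiver/target bin-mean pair under one of three
#' treatments of serial dependence:
#'
#' * `naive` — plain Pearson correlation of the binned series.
#' * `prewhiten` — each series is filtered by its own Yule-Walker AR fit of
#'   order `ar_order` ([yule_walker_ar()], [prewhiten()]) and the residuals
#'   are correlated.
#' * `ar_error_model` (default) — the perceiver series is regressed on the
#'   target series with AR(`ar_order`) errors estimated in two stages: OLS
#'   residuals give a Yule-Walker AR fit, both series are quasi-differenced by
#'   that filter, and the correlation of the transformed series is returned
#'   (equal to `sign(slope) * sqrt(R^2)` of the transformed regression).
#'
#' @param perceiver,target Equal-length numeric vectors (aligned bin means).
#' @param method Serial-dependence treatment; see Details.
#' @param ar_order AR order for the two model-based methods (0-4; 0 reduces
#'   every method to `naive`).
#' @return A single correlation in `[-1, 1]`.
#' @export
ea_correlation <- function(perceiver, target,
                           method = c("ar_error_model", "prewhiten", "naive"),
                           ar_order = 1) {
  method <- match.arg(method)
  n <- length(perceiver)
  if (length(target) != n) abort("series lengths differ.")
  if (!is.numeric(ar_order) || ar_order < 0 || ar_order > 4) {
    abort("`ar_order` must be an integer in 0..4.")
  }
  ar_order <- as.integer(ar_order)
  if (n < max(3L, ar_order + 3L)) {
    abort(sprintf("need at least %d paired bins.", max(3L, ar_order + 3L)),
          class = "eapipe_degenerate_pair")
  }
  check_not_constant <- function(x, who) {
    if (sd(x) == 0) {
      abort(sprintf("%s series is constant: correlation undefined.", who),
            class = "eapipe_degenerate_series")
    }
  }
  check_not_constant(perceiver, "perceiver")
  check_not_constant(target, "target")
  if (ar_order == 0L) method <- "naive"
  r <- switch(method,
    naive = cor(perceiver, target),
    prewhiten = {
      pe <- prewhiten(perceiver, yule_walker_ar(perceiver, ar_order))
      te <- prewhiten(target, yule_walker_ar(target, ar_order))
      check_not_constant(pe, "prewhitened perceiver")
      check_not_constant(te, "prewhitened target")
      cor(pe, te)
    },
    ar_error_model = {
      ols <- lm(perceiver ~ target)
      res <- stats::residuals(ols)
      if (sd(res) == 0) {
        # exact linear relation: correlation is +/- 1 by the slope sign
        sign(coef(ols)[2])
      } else {
        efit <- yule_walker_ar(as.numeric(res), ar_order)
        pq <- quasi_difference(perceiver, efit$coefficients)
        tq <- quasi_difference(target, efit$coefficients)
        check_not_constant(pq, "transformed perceiver")
        check_not_constant(tq, "transformed target")
        cor(pq, tq)
      }
    }
  )
  unname(r)
}

# y*_t = y_t - sum_k phi_k y_{t-k}, t > order.
quasi_difference <- function(x, phi) {
  p <- length(phi)
  n <- length(x)
  if (p == 0L) return(x)
  out <- x[(p + 1):n]
  for (k in seq_len(p)) {
    out <- out - phi[k] * x[(p + 1 - k):(n - k)]
  }
  out
}

#' Score every perceiver-by-clip pair of a study
#'
#' Runs [align_pair()] and [ea_correlation()] over all assigned pairs and
#' attaches the Fisher-z transform. Pairs that cannot be scored (missing
#' stream, too few bins, constant series) are retained as excluded rows with
#' a reason; the pipeline never drops them silently.
#'
#' @param binned Binned-series table covering perceiver and target streams
#'   (as from [preprocess_streams()]).
#' @param clips Clip-metadata table (`clip_id`, `valence`, `target_sex`,
#'   `target_id`).
#' @param assignments Tibble with `perceiver_id` and `clip_id`, one row per
#'   pair to score.
#' @param method,ar_order Passed to [ea_correlation()].
#' @param clip_at Correlation clipping bound for [fisher_z()].
#' @return An EA-score tibble: `perceiver_id`, `clip_id`, `valence`,
#'   `target_sex`, `r`, `z`, `n_bins`, `method`, `excluded`, `reason`.
#' @export
score_dataset <- function(binned, clips, assignments,
                          method = c("ar_error_model", "prewhiten", "naive"),
                          ar_order = 1, clip_at = 0.999) {
  method <- match.arg(method)
  require_columns(assignments, c("perceiver_id", "clip_id"), "`assignments`")
  require_columns(clips, c("clip_id", "valence", "target_sex"), "`clips`")
  if (nrow(assignments) == 0) {
    return(tibble(perceiver_id = character(), clip_id = character(),
                  valence = character(), target_sex = character(),
                  r = numeric(), z = numeric(), n_bins = integer(),
                  method = character(), excluded = logical(),
                  reason = character()))
  }
  require_columns(binned, c("clip_id", "rater_id", "role", "bin_index",
                            "bin_mean"), "`binned`")
  key <- paste(binned$clip_id, binned$rater_id, sep = "\r")
  series <- split(seq_len(nrow(binned)), key)
  get_series <- function(cid, rid) {
    idx <- series[[paste(cid, rid, sep = "\r")]]
    if (is.null(idx)) NULL else binned[idx, , drop = FALSE]
  }
  target_of <- setNames(clips$target_id, clips$clip_id)
  rows <- purrr::map2(assignments$perceiver_id, assignments$clip_id,
                      function(pid, cid) {
    base <- tibble(perceiver_id = pid, clip_id = cid,
                   r = NA_real_, z = NA_real_, n_bins = NA_integer_,
                   method = method, excluded = TRUE, reason = NA_character_)
    p <- get_series(cid, pid)
    t <- get_series(cid, target_of[[cid]])
    if (is.null(p) || is.null(t)) {
      base$reason <- "missing"
      return(base)
    }
    tryCatch({
      pair <- align_pair(p, t)
      r <- ea_correlation(pair$perceiver, pair$target,
                          method = method, ar_order = ar_order)
      base$r <- r
      base$z <- fisher_z(r, clip_at = clip_at)
      base$n_bins <- pair$n
      base$excluded <- FALSE
      base
    },
    eapipe_degenerate_pair = function(e) {
      base$reason <- "too_short"
      base
    },
    eapipe_degenerate_series = function(e) {
      base$reason <- "constant"
      base
    })
  })
  list_rbind(rows) |>
    left_join(select(clips, "clip_id", "valence", "target_sex"),
              by = "clip_id") |>
    select("perceiver_id", "clip_id", "valence", "target_sex",
           "r", "z", "n_bins", "method", "excluded", "reason")
}

#' Summarise an EA table
#'
#' Mean tracking correlation (and Fisher z) overall, by clip valence, and by
#' target sex, over the non-excluded rows.
#'
#' @param ea An EA-score tibble from [score_dataset()].
#' @return A tibble with columns `group`, `level`, `n`, `mean_r`, `mean_z`.
#' @export
ea_summary <- function(ea) {
  ok <- dplyr::filter(ea, !.data$excluded)
  one <- function(group, level, d) {
    tibble(group = group, level = level, n = nrow(d),
           mean_r = mean(d$r), mean_z = mean(d$z))
  }
  bind_rows(
    one("overall", "all", ok),
    ok |> group_by(.data$valence) |> dplyr::group_map(
      ~ one("valence", .y$valence, .x)) |> list_rbind(),
    ok |> group_by(.data$target_sex) |> dplyr::group_map(
      ~ one("target_sex", .y$target_sex, .x)) |> list_rbind()
  )
}
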