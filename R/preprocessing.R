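#' Average a rating stream over fixed-width time bins
#'
#' Groups samples into half-open windows `[k * bin_s, (k+1) * bin_s)` anchored
#' at the stream's first timestamp and averages within each window. A trailing
#' window covering less than a full `bin_s` of recording is dropped; the
#' recording is taken to extend one median inter-sample interval past the last
#' sample, so a 120-s stream sampled at 1 Hz yields 24 complete 5-s bins.
#'
#' @param stream A rating-stream tibble with at least `t_s` and `value`;
#'   `clip_id`, `rater_id`, `role` are carried through when present.
#' @param bin_s Bin width in seconds (> 0); default 5.
#' @return A binned-series tibble with columns `clip_id`, `rater_id`, `role`,
#'   `bin_index` (0-based, contiguous), `bin_mean`, `n_samples`.
#' @export
bin_stream <- function(stream, bin_s = 5) {
  require_columns(stream, c("t_s", "value"), "`stream`")
  if (nrow(stream) == 0) {
    abort("empty stream.", class = "eapipe_invalid_input")
  }
  assert_scalar_number(bin_s, "bin_s", lower = 0, strict_lower = TRUE)
  t0 <- stream$t_s[1]
  rel <- stream$t_s - t0
  dt <- if (nrow(stream) > 1) stats::median(diff(stream$t_s)) else bin_s
  duration <- rel[length(rel)] + dt
  idx <- floor(rel / bin_s)
  keep_max <- floor(duration / bin_s) - 1  # last fully covered window
  agg <- tibble(bin_index = idx, value = stream$value) |>
    dplyr::filter(.data$bin_index <= keep_max) |>
    group_by(.data$bin_index) |>
    summarise(bin_mean = mean(.data$value), n_samples = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$bin_index)
  tibble(
    clip_id = (stream$clip_id %||% NA_character_)[1],
    rater_id = (stream$rater_id %||% NA_character_)[1],
    role = (stream$role %||% NA_character_)[1],
    bin_index = as.integer(agg$bin_index),
    bin_mean = agg$bin_mean,
    n_samples = as.integer(agg$n_samples)
  )
}

#' Discard edge bins from a binned series
#'
#' Removes the first and last `n_edge_bins` bins (the default drops one 5-s
#' bin from each end, i.e. the first and final 5 seconds of the rating) and
#' re-zeros `bin_index`.
#'
#' @param binned A binned-series tibble for a single stream.
#' @param n_edge_bins Bins removed from each end (default 1).
#' @return The truncated binned-series tibble.
#' @export
truncate_edges <- function(binned, n_edge_bins = 1) {
  require_columns(binned, c("bin_index", "bin_mean"), "`binned`")
  n <- nrow(binned)
  if (n <= 2 * n_edge_bins) {
    abort(
      sprintf("series has %d bins; need more than %d to truncate edges.",
              n, 2 * n_edge_bins),
      class = "eapipe_too_short"
    )
  }
  out <- binned[(n_edge_bins + 1):(n - n_edge_bins), , drop = FALSE]
  out$bin_index <- seq_len(nrow(out)) - 1L
  out
}

#' Pair a perceiver and a target binned series for correlation
#'
#' Aligns two truncated binned series for the same clip from bin 0, trimming
#' both to the shorter common length. A length mismatch greater than 2 bins
#' triggers a warning (dial logs occasionally end a few samples early); a
#' common length below 3 is degenerate and raises an error.
#'
#' @param perceiver,target Binned-series tibbles sharing a `clip_id`.
#' @return A list with numeric vectors `perceiver` and `target`, the paired
#'   length `n`, and `clip_id`.
#' @export
align_pair <- function(perceiver, target) {
  require_columns(perceiver, c("clip_id", "bin_index", "bin_mean"),
                  "`perceiver`")
  require_columns(target, c("clip_id", "bin_index", "bin_mean"), "`target`")
  cid_p <- perceiver$clip_id[1]
  cid_t <- target$clip_id[1]
  if (!identical(cid_p, cid_t)) {
    abort(sprintf("clip_id mismatch: '%s' vs '%s'.", cid_p, cid_t),
          class = "eapipe_invalid_pairing")
  }
  n <- min(nrow(perceiver), nrow(target))
  if (abs(nrow(perceiver) - nrow(target)) > 2) {
    warn(sprintf("clip %s: series lengths differ by more than 2 bins (%d vs %d).",
                 cid_p, nrow(perceiver), nrow(target)))
  }
  if (n < 3) {
    abort(sprintf("clip %s: fewer than 3 paired bins.", cid_p),
          class = "eapipe_degenerate_pair")
  }
  p <- arrange(perceiver, .data$bin_index)$bin_mean[seq_len(n)]
  t <- arrange(target, .data$bin_index)$bin_mean[seq_len(n)]
  list(perceiver = p, target = t, n = n, clip_id = cid_p)
}

#' Validate a rating stream
#'
#' Report-only checks: dial values inside `[1, 9]`, strictly increasing
#' timestamps, minimum duration, and a constant-series flag (a constant
#' perceiver trace has no defined tracking correlation). Never raises.
#'
#' @param stream A rating-stream tibble.
#' @param min_duration_s Minimum acceptable duration in seconds.
#' @return A tibble of violations with columns `check` and `message`; zero
#'   rows for a clean stream.
#' @export
validate_stream <- function(stream, min_duration_s = 30) {
  issues <- list()
  add <- function(check, message) {
    issues[[length(issues) + 1]] <<- tibble(check = check, message = message)
  }
  if (is.null(stream) || nrow(stream) == 0) {
    add("empty", "stream has no samples")
    return(list_rbind(issues))
  }
  if (any(stream$value < 1 | stream$value > 9, na.rm = TRUE)) {
    add("out_of_range",
        sprintf("%d value(s) outside [1, 9]",
                sum(stream$value < 1 | stream$value > 9, na.rm = TRUE)))
  }
  if (any(is.na(stream$value))) add("missing_values", "NA dial values present")
  if (nrow(stream) > 1 && any(diff(stream$t_s) <= 0)) {
    add("non_monotone", "timestamps not strictly increasing")
  }
  dur <- diff(range(stream$t_s))
  if (dur < min_duration_s) {
    add("too_short", sprintf("duration %.1f s below minimum %.1f s",
                             dur, min_duration_s))
  }
  if (nrow(stream) > 1 && sd(stream$value) == 0) {
    add("constant_series",
        "constant series: tracking correlation undefined downstream")
  }
  if (length(issues) == 0) {
    tibble(check = character(), message = character())
  } else {
    list_rbind(issues)
  }
}

#' Bin and truncate every stream in a long table
#'
#' Applies [bin_stream()] and [truncate_edges()] per `(clip_id, rater_id)`
#' group. Streams too short to survive edge truncation are excluded with a
#' warning and listed in the `excluded` attribute of the result.
#'
#' @param streams Long rating-stream table (`clip_id`, `rater_id`, `role`,
#'   `t_s`, `value`).
#' @param bin_s Bin width in seconds.
#' @param n_edge_bins Bins discarded from each end.
#' @return Binned-series tibble for all surviving streams; attribute
#'   `excluded` holds a tibble of dropped streams and reasons.
#' @export
preprocess_streams <- function(streams, bin_s = 5, n_edge_bins = 1) {
  require_columns(streams, c("clip_id", "rater_id", "t_s", "value"),
                  "`streams`")
  groups <- streams |>
    group_by(.data$clip_id, .data$rater_id) |>
    dplyr::group_split()
  excluded <- list()
  kept <- purrr::map(groups, function(g) {
    tryCatch(
      truncate_edges(bin_stream(g, bin_s = bin_s), n_edge_bins = n_edge_bins),
      eapipe_too_short = function(e) {
        excluded[[length(excluded) + 1]] <<- tibble(
          clip_id = g$clip_id[1], rater_id = g$rater_id[1],
          reason = conditionMessage(e)
        )
        NULL
      }
    )
  })
  excl <- if (length(excluded)) list_rbind(excluded) else
    tibble(clip_id = character(), rater_id = character(),
           reason = character())
  if (nrow(excl) > 0) {
    warn(sprintf("%d stream(s) too short after binning; excluded.",
                 nrow(excl)))
  }
  out <- list_rbind(purrr::compact(kept))
  attr(out, "excluded") <- excl
  out
}
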