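#' Sample a constraint-respecting clip presentation order
#'
#' Orders a set of clips pseudo-randomly under the presentation constraints
#' used in empathic-accuracy tasks: the same target appears at most
#' `max_target_repeats` times in the list, and no more than `max_valence_run`
#' clips of the same valence run consecutively.
#'
#' The sampler first tries rejection sampling from uniformly random
#' permutations (exactly uniform among feasible orders when it succeeds) and
#' falls back to backtracking with randomized candidate order for tightly
#' constrained sets. If exhaustive backtracking finds no feasible order an
#' `eapipe_infeasible_order` error is raised.
#'
#' @param clips Clip-metadata tibble with `clip_id`, `target_id`, `valence`.
#' @param max_target_repeats Maximum appearances of any single target.
#' @param max_valence_run Maximum run length of identical valence.
#' @param seed Integer seed.
#' @param max_rejection_tries Uniform-permutation attempts before falling
#'   back to backtracking.
#' @return The `clips` tibble reordered, with a `position` column.
#' @export
sample_clip_order <- function(clips, max_target_repeats = 2,
                              max_valence_run = 2, seed = NULL,
                              max_rejection_tries = 200) {
  require_columns(clips, c("clip_id", "target_id", "valence"), "`clips`")
  n <- nrow(clips)
  if (n == 0) abort("`clips` is empty.")
  ok <- function(ord) {
    order_feasible(clips$target_id[ord], clips$valence[ord],
                   max_target_repeats, max_valence_run)
  }
  ord <- with_seed(seed, {
    found <- NULL
    if (max(table(clips$target_id)) <= max_target_repeats) {
      for (try in seq_len(max_rejection_tries)) {
        cand <- sample(n)
        if (ok(cand)) {
          found <- cand
          break
        }
      }
    }
    found %||% backtrack_order(clips$target_id, clips$valence,
                               max_target_repeats, max_valence_run)
  })
  if (is.null(ord)) {
    abort("no clip order satisfies the presentation constraints.",
          class = "eapipe_infeasible_order")
  }
  out <- clips[ord, , drop = FALSE]
  out$position <- seq_len(n)
  out
}

order_feasible <- function(targets, valences, max_target_repeats,
                           max_valence_run) {
  if (max(table(targets)) > max_target_repeats) return(FALSE)
  r <- rle(valences)
  all(r$lengths <= max_valence_run)
}

# Depth-first search over positions; candidates shuffled at each level so the
# first solution found is randomized. Returns an index vector or NULL.
backtrack_order <- function(targets, valences, max_target_repeats,
                            max_valence_run) {
  n <- length(targets)
  if (max(table(targets)) > max_target_repeats) return(NULL)
  used <- rep(FALSE, n)
  ord <- integer(n)
  recurse <- function(depth, run_val, run_len) {
    if (depth > n) return(TRUE)
    cands <- sample(which(!used))
    for (i in cands) {
      v <- valences[i]
      new_run <- if (identical(v, run_val)) run_len + 1L else 1L
      if (new_run > max_valence_run) next
      used[i] <<- TRUE
      ord[depth] <<- i
      if (recurse(depth + 1L, v, new_run)) return(TRUE)
      used[i] <<- FALSE
    }
    FALSE
  }
  if (recurse(1L, NA_character_, 0L)) ord else NULL
}
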