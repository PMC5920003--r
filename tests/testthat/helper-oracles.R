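# Independent oracles and small fixtures used across tests.

# Brute-force checker for clip presentation constraints: target counts and
# valence run lengths, computed directly from the ordered tibble.
order_satisfies_constraints <- function(ordered, max_target_repeats = 2,
                                        max_valence_run = 2) {
  counts_ok <- all(table(ordered$target_id) <= max_target_repeats)
  runs <- rle(ordered$valence)$lengths
  counts_ok && all(runs <= max_valence_run)
}

# Direct linear solve of the Yule-Walker system on biased sample
# autocovariances: R phi = r, with R the Toeplitz autocovariance matrix.
yw_direct_solve <- function(series, order) {
  n <- length(series)
  x <- series - mean(series)
  acov <- vapply(0:order, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n
  }, numeric(1))
  R <- stats::toeplitz(acov[1:order])
  solve(R, acov[2:(order + 1)])
}

# AR(1) series generator used by scoring tests.
ar1_series <- function(n, phi, sd = 1) {
  as.numeric(stats::filter(rnorm(n, 0, sd), phi, method = "recursive",
                           init = rnorm(1, 0, sd / sqrt(1 - phi^2))))
}

# Constant-rate rating stream around a path, for preprocessing tests.
make_stream <- function(values, rate_hz = 1, clip_id = "C01",
                        rater_id = "P001", role = "perceiver", t0 = 0) {
  tibble::tibble(
    clip_id = clip_id, rater_id = rater_id, role = role,
    t_s = t0 + (seq_along(values) - 1) / rate_hz,
    value = values
  )
}

# Small study cohort reused by scoring/pipeline tests (4 perceivers x 4
# clips keeps stream synthesis cheap).
small_cohort <- function(seed = 42, ...) {
  generate_cohort(n_perceivers = 4, n_clips = 4,
                  clip_set = default_clip_set(n_targets = 4),
                  seed = seed, ...)
}
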