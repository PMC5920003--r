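#' Fit an autoregressive model by the Yule-Walker method
#'
#' Solves the Yule-Walker equations on biased sample autocovariances of the
#' demeaned series via the Levinson-Durbin recursion. The biased (divide by
#' n) autocovariance convention guarantees a positive-definite system, hence
#' a stationary fitted model.
#'
#' @param series Numeric vector, longer than `order + 2`, not constant.
#' @param order AR order (>= 0).
#' @return An object of class `ar_fit`: list with `order`, `coefficients`
#'   (length `order`), `innovation_variance`, `n_obs`, and the series `mean`
#'   used for demeaning.
#' @export
yule_walker_ar <- function(series, order = 1) {
  if (!is.numeric(series) || any(!is.finite(series))) {
    abort("`series` must be finite numeric.")
  }
  n <- length(series)
  if (!is.numeric(order) || order < 0 || order != round(order)) {
    abort("`order` must be a nonnegative integer.")
  }
  order <- as.integer(order)
  if (order >= n - 2) {
    abort("`order` must be smaller than length(series) - 2.")
  }
  mu <- mean(series)
  x <- series - mu
  if (sd(series) == 0) {
    abort("constant series: autoregression undefined.",
          class = "eapipe_degenerate_series")
  }
  # biased sample autocovariances c_0 .. c_order
  acov <- vapply(0:order, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n
  }, numeric(1))
  ld <- levinson_durbin(acov)
  structure(
    list(order = order,
         coefficients = ld$phi,
         innovation_variance = ld$sigma2,
         n_obs = n,
         mean = mu),
    class = "ar_fit"
  )
}

# Levinson-Durbin recursion on an autocovariance sequence c_0..c_p.
# Returns phi (length p) and the innovation variance after p steps.
levinson_durbin <- function(acov) {
  p <- length(acov) - 1L
  if (p == 0L) return(list(phi = numeric(0), sigma2 = acov[1]))
  phi <- numeric(p)
  prev <- numeric(0)
  sigma2 <- acov[1]
  for (m in seq_len(p)) {
    num <- acov[m + 1]
    if (m > 1) num <- num - sum(prev * acov[m:2])
    k <- num / sigma2
    phi_m <- c(prev - k * rev(prev), k)
    sigma2 <- sigma2 * (1 - k^2)
    prev <- phi_m
  }
  list(phi = prev, sigma2 = sigma2)
}

#' Filter a series by a fitted AR model
#'
#' Returns the one-step prediction residuals
#' `e_t = x_t - sum_k phi_k x_{t-k}` for `t > order`, computed on the series
#' centered at the fit's mean (an order-0 fit therefore returns the centered
#' series unchanged). Output length is `length(series) - order`.
#'
#' @param series Numeric vector.
#' @param fit An `ar_fit` (or any list with `order`, `coefficients`, and
#'   optionally `mean`; when `mean` is absent the series mean is used).
#' @return Numeric residual vector.
#' @export
prewhiten <- function(series, fit) {
  p <- fit$order
  n <- length(series)
  if (n <= p) abort("series shorter than the AR order.")
  x <- series - (fit$mean %||% mean(series))
  if (p == 0L) return(x)
  e <- x[(p + 1):n]
  for (k in seq_len(p)) {
    e <- e - fit$coefficients[k] * x[(p + 1 - k):(n - k)]
  }
  e
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("Yule-Walker AR(%d) fit on %d observations\n", x$order, x$n_obs))
  if (x$order > 0) {
    cat("coefficients:", paste(sprintf("%.4f", x$coefficients),
                               collapse = " "), "\n")
  }
  cat(sprintf("innovation variance: %.4f\n", x$innovation_variance))
  invisible(x)
}
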