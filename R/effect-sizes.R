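#' Cohen's d from a single-numerator-df F statistic
#'
#' For a fixed effect tested with numerator df 1 in a two-group (or
#' single-slope) design, `d = 2 * sqrt(F / df_den)`. This is the conversion
#' behind effect sizes reported alongside mixed-model F tests.
#'
#' @param f F statistic (>= 0; vectorized).
#' @param df_den Denominator degrees of freedom (>= 1).
#' @return Cohen's d (unsigned).
#' @examples
#' cohens_d_from_f(17.86, 53)  # 1.16
#' @export
cohens_d_from_f <- function(f, df_den) {
  if (any(f < 0, na.rm = TRUE)) abort("`f` must be nonnegative.")
  if (any(df_den < 1, na.rm = TRUE)) abort("`df_den` must be >= 1.")
  2 * sqrt(f / df_den)
}

#' Cohen's d from a t statistic
#'
#' `d = 2 * |t| / sqrt(df)`, the standard conversion for a between-subject
#' contrast.
#'
#' @param t t statistic (vectorized; sign ignored).
#' @param df Degrees of freedom (>= 1).
#' @return Cohen's d (unsigned).
#' @examples
#' cohens_d_from_t(-2.44, 50)  # 0.69
#' @export
cohens_d_from_t <- function(t, df) {
  if (any(df < 1, na.rm = TRUE)) abort("`df` must be >= 1.")
  2 * abs(t) / sqrt(df)
}
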