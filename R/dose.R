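#' Vodka volume for a per-weight alcohol dose
#'
#' Computes the volume of vodka needed to deliver a weight-proportional
#' moderate alcohol dose, split equally over two glasses. Two dosing
#' conventions are supported: `ml_per_kg` treats the dose as millilitres of
#' pure ethanol per kg of body weight (`weight * dose / abv`); `g_per_kg`
#' treats it as grams of ethanol per kg and divides additionally by the
#' density of ethanol (`weight * dose / (abv * ethanol_density)`).
#'
#' @param weight_kg Body weight in kg (> 0; vectorized).
#' @param dose Dose per kg of body weight; default 0.56.
#' @param abv Alcohol by volume of the spirit as a fraction; default 0.375.
#' @param convention `"ml_per_kg"` or `"g_per_kg"`.
#' @param ethanol_density Density of ethanol in g/ml; default 0.789.
#' @return A tibble with columns `weight_kg`, `convention`, `total_ml`,
#'   `glass_ml` (half the total, two glasses).
#' @examples
#' compute_vodka_volume(c(57, 100))
#' @export
compute_vodka_volume <- function(weight_kg, dose = 0.56, abv = 0.375,
                                 convention = c("ml_per_kg", "g_per_kg"),
                                 ethanol_density = 0.789) {
  convention <- match.arg(convention)
  if (!is.numeric(weight_kg) || any(!is.finite(weight_kg)) ||
      any(weight_kg <= 0)) {
    abort("`weight_kg` must be positive.")
  }
  if (!is.numeric(abv) || abv <= 0 || abv > 1) {
    abort("`abv` must be a fraction in (0, 1].")
  }
  total <- switch(convention,
    ml_per_kg = weight_kg * dose / abv,
    g_per_kg = weight_kg * dose / (abv * ethanol_density)
  )
  tibble(
    weight_kg = weight_kg,
    convention = convention,
    total_ml = total,
    glass_ml = total / 2
  )
}
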