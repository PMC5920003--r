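#' Simple-slopes interaction plot
#'
#' Predicted Fisher-z empathic accuracy by condition at moderator levels one
#' SD below and above the mean — the standard way to display a
#' condition-by-moderator interaction.
#'
#' @param model An `ea_model` fitted with a moderator
#'   (see [fit_mixed_model()]).
#' @param sd_multipliers Moderator levels in SD units (default `c(-1, 1)`).
#' @return A ggplot object.
#' @export
plot_simple_slopes <- function(model, sd_multipliers = c(-1, 1)) {
  stopifnot(inherits(model, "ea_model"))
  mi <- model$moderator
  if (is.null(mi)) {
    abort("model has no moderator; nothing to plot.",
          class = "eapipe_invalid_request")
  }
  b <- model$fixed_effects$estimate
  names(b) <- model$fixed_effects$term
  cn <- names(b)
  j_int <- which(cn == "(Intercept)")
  j_mod <- which(cn == "moderator_c")
  j_foc <- which(startsWith(cn, mi$focal) & !grepl(":", cn, fixed = TRUE))
  j_ix <- which(grepl(":", cn, fixed = TRUE) &
                  grepl("moderator_c", cn, fixed = TRUE))
  focal_levels <- levels(model$data[[mi$focal]]) %||%
    unique(model$data[[mi$focal]])
  cells <- tidyr::expand_grid(
    mult = sd_multipliers,
    focal = factor(focal_levels, levels = focal_levels)
  ) |>
    mutate(
      moderator_level = sprintf("%s (mean %+g SD)", mi$name, .data$mult),
      predicted_z = b[j_int] + .data$mult * mi$sd * b[j_mod] +
        (as.integer(.data$focal) - 1) *
          (b[j_foc] + .data$mult * mi$sd * b[j_ix])
    )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$focal,
                                      y = .data$predicted_z,
                                      group = .data$moderator_level,
                                      linetype = .data$moderator_level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = mi$focal, y = "Empathic accuracy (Fisher z)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_mixed_model Plot method: simple-slopes display when the
#'   model carries a moderator, otherwise a coefficient dot-whisker plot.
#' @param object An `ea_model`.
#' @method autoplot ea_model
#' @export
autoplot.ea_model <- function(object, ...) {
  if (!is.null(object$moderator)) {
    return(plot_simple_slopes(object))
  }
  fe <- dplyr::filter(object$fixed_effects, .data$term != "(Intercept)")
  ggplot2::ggplot(fe, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Estimate (Fisher z)", y = NULL) +
    ggplot2::theme_minimal()
}
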