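# ggplot2 views of scored ensembles and fitted trendlines.

#' Plot a scored complex ensemble
#'
#' Scatter of a chosen descriptor against the ASF score, colored by filter
#' verdict -- the plot used to eyeball whether a descriptor drives the
#' score across an ensemble.
#'
#' @param object An `asf_results` tibble from [score_complexes()].
#' @param x Descriptor column to place on the x axis (default `"abl_A"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asf_results <- function(object, x = "abl_A", ...) {
  if (!x %in% names(object)) {
    abort_asf(paste0("No column '", x, "' in the results."),
              "asfscreen_config_error")
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x]], y = .data$asf,
                               colour = .data$passed)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      name = "passes filters"
    ) +
    ggplot2::labs(x = x, y = "ASF (J·m/Debye)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted trendline
#'
#' The fitted points with the trendline evaluated over the x range, and the
#' family and R^2 in the subtitle.
#'
#' @param object An `asf_fit` from [fit_relation()].
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asf_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(
    x = seq(min(object$data$x), max(object$data$x), length.out = n_grid)
  )
  grid$.fitted <- predict(object, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$.fitted),
                       colour = "#2166ac") +
    ggplot2::labs(
      subtitle = sprintf("%s fit, R² = %.4f, n = %d",
                         object$family, object$r_squared, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rank-paired log-log correlation
#'
#' @param object An `asf_sorted_correlation` from [sorted_log_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asf_sorted_correlation <- function(object, ...) {
  p <- autoplot(object$fit)
  p + ggplot2::labs(x = "log10(ASF)", y = "log10(activity)",
                    caption = paste(object$warnings, collapse = "\n"))
}

#' Plot complexes on the solvent polarity ladder
#'
#' Reference solvents as labeled vertical lines on the D/V axis, with the
#' ensemble's D/V values as points -- a visual polarity-adaptivity check.
#'
#' @param results An `asf_results` tibble (anything with a `dv` column).
#' @param ladder Solvent reference tibble (default [solvent_ladder()]).
#' @return A ggplot object.
#' @export
plot_polarity_ladder <- function(results, ladder = solvent_ladder()) {
  ggplot2::ggplot() +
    ggplot2::geom_vline(data = ladder,
                        ggplot2::aes(xintercept = .data$dv),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_text(data = ladder,
                       ggplot2::aes(x = .data$dv, y = 1.08,
                                    label = .data$name),
                       angle = 90, hjust = 0, size = 3, colour = "grey40") +
    ggplot2::geom_jitter(data = results,
                         ggplot2::aes(x = .data$dv, y = 1),
                         width = 0, height = 0.03,
                         colour = "#2166ac", alpha = 0.7) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0.9, 1.6)) +
    ggplot2::labs(x = "D/V (Debye/Å³)") +
    ggplot2::theme_minimal()
}
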