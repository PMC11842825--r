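#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scale-dependent variance curve
#'
#' Log-log plot of variance against window length.
#'
#' @param object A `scale_variance_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot scale_variance_curve
#' @export
autoplot.scale_variance_curve <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$v), .data$v > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$window_samples, .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window length L (samples)", y = "variance V") +
    ggplot2::theme_minimal()
}

#' Plot a variance-slope fit
#'
#' The scale-dependent variance curve with the fitted power law overlaid;
#' the fitted slope is the variance slope.
#'
#' @param object A `variance_slope_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot variance_slope_fit
#' @export
autoplot.variance_slope_fit <- function(object, ...) {
  p <- autoplot.scale_variance_curve(object$curve)
  if (object$valid) {
    p <- p +
      ggplot2::geom_abline(slope = object$gamma, intercept = object$intercept,
                           colour = "red3", linetype = 2) +
      ggplot2::labs(subtitle = sprintf("variance slope = %.2f, R² = %.2f",
                                       object$gamma, object$r_squared))
  }
  p
}

#' Plot a variance-slope versus Fourier-slope ensemble
#'
#' @param object A `gamma_slope_map`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot gamma_slope_map
#' @export
autoplot.gamma_slope_map <- function(object, ...) {
  co <- stats::coef(object$fit)
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$slope, .data$gamma)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = co[1], slope = co[2], colour = "red3") +
    ggplot2::labs(x = "Fourier spectral slope", y = "variance slope") +
    ggplot2::theme_minimal()
}

#' Plot a spatial correlogram of the variance slope
#'
#' @param object A `gamma_correlogram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot gamma_correlogram
#' @export
autoplot.gamma_correlogram <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_mid_km, .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "centroid separation (km)", y = "pair correlation of variance slope") +
    ggplot2::theme_minimal()
}

#' Scatter of per-leg variance slopes for two variables
#'
#' @param table A [gamma_table()].
#' @param var_a,var_b Variable names.
#' @return A ggplot of the per-leg slope pairs with an OLS line.
#' @export
plot_gamma_comparison <- function(table, var_a, var_b) {
  wide <- gamma_pairs(table, var_a, var_b)
  ggplot2::ggplot(wide, ggplot2::aes(.data[[var_a]], .data[[var_b]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red3", linewidth = 0.5) +
    ggplot2::labs(x = bquote(Gamma[.(var_a)]), y = bquote(Gamma[.(var_b)])) +
    ggplot2::theme_minimal()
}
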