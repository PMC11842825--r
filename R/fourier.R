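#' Fourier spectral slope of a gapless leg
#'
#' Log-log least-squares slope of the periodogram of the mean-removed
#' series over the wavenumbers whose wavelengths fall inside the window
#' scheme's spatial range (3 to 500 samples by default). Negative for red
#' spectra; the classical inertial-subrange value is -5/3. Requires a
#' complete series — for gappy legs use the variance slope ([leg_gamma()])
#' instead, which is the point of that statistic.
#'
#' @param x Numeric leg values, no `NA`.
#' @param scheme A [window_scheme()]; its endpoints set the fitted
#'   wavenumber range.
#' @param taper `"none"` (plain periodogram, the conventional estimator)
#'   or `"hann"`. The plain periodogram cannot resolve slopes steeper than
#'   about -2 (spectral leakage from a rectangular window); use the Hann
#'   taper when slopes near -3 must be measured.
#' @param dx_km Optional along-track step; only affects the reported
#'   frequency units, not the slope.
#' @return A single numeric slope (d log10 power / d log10 wavenumber).
#' @export
fourier_slope <- function(x, scheme = window_scheme(),
                          taper = c("none", "hann"), dx_km = NULL) {
  taper <- match.arg(taper)
  x <- as.numeric(x)
  if (anyNA(x))
    stop_config("series contains missing values; the Fourier path needs a complete series (use leg_gamma() for gappy legs)")
  n <- length(x)
  if (n < 8L) stop_config("series too short for a spectral fit")
  x <- x - mean(x)
  if (taper == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
    x <- x * w
  }
  pgram <- Mod(stats::fft(x))^2 / n
  k <- seq_len(n %/% 2L)
  keep <- k >= n / max(scheme) & k <= n / min(scheme)
  if (sum(keep) < 3L) stop_config("fewer than 3 wavenumbers in the scheme's range")
  kk <- k[keep]
  p <- pgram[1L + kk]
  pos <- p > 0
  fit <- stats::lm.fit(cbind(1, log10(kk[pos])), log10(p[pos]))
  unname(fit$coefficients[2])
}

#' Empirical map between variance slope and Fourier spectral slope
#'
#' Fits the linear relation between per-leg variance slope and per-leg
#' Fourier spectral slope across an ensemble, and evaluates it at any
#' query slope. Evaluated at the classical -5/3 inertial-subrange slope,
#' the map gives the corresponding variance slope (about 0.84 for gapless
#' 500-sample power-law legs spanning spectral slopes -1 to -3).
#'
#' @param pairs Data frame with columns `gamma` (variance slope) and
#'   `slope` (Fourier slope), one row per leg; at least 20 rows.
#' @return Object of class `"gamma_slope_map"` wrapping the OLS fit; use
#'   [predict_gamma()] to evaluate it, or [generics::tidy()] /
#'   [generics::glance()] for the coefficients.
#' @examples
#' cfgs <- lapply(seq(1, 3, length.out = 40), function(b)
#'   transect_config(beta = b, seed = round(100 * b)))
#' legs <- lapply(cfgs, gen_powerlaw_series)
#' pairs <- data.frame(
#'   gamma = vapply(legs, function(x) leg_gamma(x)$gamma, 1),
#'   slope = vapply(legs, fourier_slope, 1)
#' )
#' m <- gamma_slope_map(pairs)
#' predict_gamma(m, -5/3)
#' @export
gamma_slope_map <- function(pairs) {
  if (!all(c("gamma", "slope") %in% names(pairs)))
    stop_config("`pairs` must have `gamma` and `slope` columns")
  pairs <- pairs[stats::complete.cases(pairs[c("gamma", "slope")]), ]
  if (nrow(pairs) < 20L)
    stop_config("need at least 20 (gamma, slope) pairs, got %d", nrow(pairs))
  if (stats::sd(pairs$slope) < .Machine$double.eps^0.5)
    stop_config("degenerate ensemble: no spread in Fourier slopes")
  fit <- stats::lm(gamma ~ slope, data = pairs)
  structure(list(fit = fit, pairs = tibble::as_tibble(pairs)),
            class = "gamma_slope_map")
}

#' Evaluate a gamma-slope map at a query Fourier slope
#'
#' @param map A [gamma_slope_map()].
#' @param slope Fourier slope(s) at which to predict the variance slope.
#' @return Predicted variance slope(s).
#' @export
predict_gamma <- function(map, slope) {
  if (!inherits(map, "gamma_slope_map"))
    stop_config("`map` must come from gamma_slope_map()")
  unname(stats::predict(map$fit, newdata = data.frame(slope = slope)))
}

#' @export
print.gamma_slope_map <- function(x, ...) {
  co <- stats::coef(x$fit)
  cat(sprintf(
    "<gamma_slope_map> gamma = %.3f %+.3f * slope  (n = %d, r = %.3f)\n",
    co[1], co[2], nrow(x$pairs), stats::cor(x$pairs$gamma, x$pairs$slope)))
  invisible(x)
}

#' @method tidy gamma_slope_map
#' @export
tidy.gamma_slope_map <- function(x, ...) {
  tibble::as_tibble(cbind(term = c("(Intercept)", "slope"),
                          as.data.frame(summary(x$fit)$coefficients)),
                    .name_repair = ~ c("term", "estimate", "std.error",
                                       "statistic", "p.value"))
}

#' @method glance gamma_slope_map
#' @export
glance.gamma_slope_map <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma,
                 n = nrow(x$pairs),
                 gamma_at_kolmogorov = predict_gamma(x, -5/3))
}
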