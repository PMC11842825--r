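#' Log-distributed window scheme
#'
#' The set of window lengths over which scale-dependent variance is
#' evaluated: `n_windows` log-uniformly spaced points from `min_window` to
#' `max_window` samples, rounded to the nearest integer and deduplicated
#' preserving order. Both endpoints are always present. The default — 11
#' windows from 3 to 500 samples — spans roughly 0.6 km to 100 km at a
#' 0.21 km median along-track step.
#'
#' @param min_window,max_window Smallest and largest window, samples
#'   (2 <= min < max).
#' @param n_windows Number of windows before deduplication (>= 2).
#' @return Integer vector of class `"window_scheme"`.
#' @examples
#' window_scheme()                 # 3 5 8 14 23 39 65 108 180 300 500
#' window_scheme(3, 25, 5)         # the small-scale-only variant (~5 km)
#' @export
window_scheme <- function(min_window = 3, max_window = 500, n_windows = 11) {
  min_window <- check_count(min_window, "min_window", min = 2L)
  max_window <- check_count(max_window, "max_window", min = 3L)
  n_windows <- check_count(n_windows, "n_windows", min = 2L)
  if (min_window >= max_window)
    stop_config("`min_window` must be < `max_window`")
  if (n_windows > max_window - min_window + 1L)
    stop_config("`n_windows` = %d windows cannot be distinct in [%d, %d]",
                n_windows, min_window, max_window)
  sizes <- unique(as.integer(round(exp(
    seq(log(min_window), log(max_window), length.out = n_windows)))))
  structure(sizes, class = c("window_scheme", "integer"))
}

#' Gap-tolerant scale-dependent variance of a transect leg
#'
#' For each window length `w` in the scheme, the leg is partitioned into
#' consecutive non-overlapping blocks of `w` slots (trailing remainder
#' discarded). A block contributes if at least `min_block_coverage` of its
#' slots hold valid data; the variance of the valid samples is computed
#' within each contributing block and `V(w)` is the mean over contributing
#' blocks. This is what makes the statistic usable on records with gaps
#' (up to about 20% of a leg), where a Fourier spectrum is not.
#'
#' @param x Numeric leg values with `NA` marking gaps (typically 500
#'   slots).
#' @param scheme A [window_scheme()]. Windows longer than `length(x)` are
#'   dropped.
#' @param min_block_coverage Minimum valid fraction for a block to
#'   contribute (default 0.80, mirroring the leg-level coverage rule).
#' @param var_method `"sample"` (divisor n-1, the default: unbiased, so
#'   white noise yields a flat curve and a variance slope centred on zero)
#'   or `"population"` (divisor n; makes deterministic closed forms such as
#'   the unit ramp's `V(w) = (w^2-1)/12` exact).
#' @param dx_km Optional along-track step used to express windows in km.
#' @return Tibble of class `"scale_variance_curve"` with columns
#'   `window_samples`, `window_km` (`NA` if `dx_km` is missing), `v`, and
#'   `n_blocks` (contributing blocks; `v` is `NA` where no block
#'   contributes).
#' @export
scale_variance <- function(x, scheme = window_scheme(),
                           min_block_coverage = 0.8,
                           var_method = c("sample", "population"),
                           dx_km = NULL) {
  var_method <- match.arg(var_method)
  check_fraction(min_block_coverage, "min_block_coverage")
  x <- as.numeric(x)
  n <- length(x)
  if (n < min(scheme)) stop_config("leg is shorter than the smallest window")
  if (all(is.na(x))) stop_config("leg contains no valid data")
  sizes <- as.integer(scheme[scheme <= n])

  res <- purrr::map(sizes, function(w) {
    nb <- n %/% w
    m <- matrix(x[seq_len(nb * w)], nrow = w)
    nv <- colSums(!is.na(m))
    keep <- nv / w >= min_block_coverage & nv >= 2L
    if (!any(keep)) return(list(v = NA_real_, n_blocks = 0L))
    m <- m[, keep, drop = FALSE]
    nv <- nv[keep]
    mu <- colMeans(m, na.rm = TRUE)
    ss <- colSums(sweep(m, 2L, mu)^2, na.rm = TRUE)
    denom <- if (var_method == "population") nv else nv - 1L
    list(v = mean(ss / denom), n_blocks = sum(keep))
  })

  tibble::new_tibble(
    tibble::tibble(
      window_samples = sizes,
      window_km = if (is.null(dx_km)) NA_real_ else sizes * dx_km,
      v = purrr::map_dbl(res, "v"),
      n_blocks = purrr::map_int(res, "n_blocks")
    ),
    class = "scale_variance_curve"
  )
}

#' Fit the variance slope to a scale-dependent variance curve
#'
#' Ordinary least squares of `log10 V` on `log10 L` (window length in
#' samples) over the scales with positive, non-missing variance: the slope
#' is the variance slope of the power law \eqn{V = L^\Gamma}. A lower
#' slope means relatively more variance at small scales — a patchier leg.
#'
#' @param curve A `scale_variance_curve` from [scale_variance()].
#' @param weight_by_blocks If `TRUE`, weight each scale by its number of
#'   contributing blocks (default `FALSE`: unweighted, the conventional
#'   fit).
#' @return An object of class `"variance_slope_fit"`: a list with `gamma`,
#'   `intercept` (log10 variance at L = 1), `r_squared`, `n_scales_used`,
#'   `valid`, `reason`, and the input `curve`. Fewer than 2 usable scales
#'   gives `valid = FALSE` with `gamma = NA` rather than an error.
#' @seealso [leg_gamma()] for the one-call composition, [generics::tidy()]
#'   and [generics::glance()] methods, [ggplot2::autoplot()].
#' @export
fit_gamma <- function(curve, weight_by_blocks = FALSE) {
  if (!all(c("window_samples", "v") %in% names(curve)))
    stop_config("`curve` must have `window_samples` and `v` columns")
  ok <- !is.na(curve$v) & curve$v > 0
  out <- list(gamma = NA_real_, intercept = NA_real_, r_squared = NA_real_,
              n_scales_used = sum(ok), valid = FALSE, reason = NA_character_,
              curve = curve)
  if (sum(ok) < 2L) {
    out$reason <- "insufficient_scales"
    return(structure(out, class = "variance_slope_fit"))
  }
  lx <- log10(curve$window_samples[ok])
  ly <- log10(curve$v[ok])
  w <- if (weight_by_blocks) curve$n_blocks[ok] else rep(1, sum(ok))
  fit <- stats::lm.wfit(cbind(1, lx), ly, w)
  out$gamma <- unname(fit$coefficients[2])
  out$intercept <- unname(fit$coefficients[1])
  ss_tot <- sum(w * (ly - stats::weighted.mean(ly, w))^2)
  out$r_squared <- if (ss_tot > 0) 1 - sum(w * fit$residuals^2) / ss_tot else NA_real_
  out$valid <- TRUE
  out$reason <- "ok"
  structure(out, class = "variance_slope_fit")
}

#' Variance slope of a transect leg
#'
#' One-call composition of [scale_variance()] and [fit_gamma()]: the
#' package's core statistic.
#'
#' @inheritParams scale_variance
#' @inheritParams fit_gamma
#' @return A `"variance_slope_fit"` (see [fit_gamma()]).
#' @examples
#' x <- gen_powerlaw_series(transect_config(beta = 2, seed = 7))
#' fit <- leg_gamma(x)
#' fit$gamma
#' generics::tidy(fit)
#' @export
leg_gamma <- function(x, scheme = window_scheme(),
                      min_block_coverage = 0.8,
                      var_method = c("sample", "population"),
                      dx_km = NULL, weight_by_blocks = FALSE) {
  fit_gamma(
    scale_variance(x, scheme, min_block_coverage, var_method, dx_km),
    weight_by_blocks = weight_by_blocks
  )
}

#' @export
print.variance_slope_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<variance_slope_fit> gamma = %.3f  intercept = %.3f  R^2 = %.3f  (%d scales)\n",
                x$gamma, x$intercept, x$r_squared, x$n_scales_used))
  } else {
    cat(sprintf("<variance_slope_fit> invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy variance_slope_fit
#' @export
tidy.variance_slope_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log10_window", "intercept"),
    estimate = c(x$gamma, x$intercept)
  )
}

#' @method glance variance_slope_fit
#' @export
glance.variance_slope_fit <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, intercept = x$intercept, r_squared = x$r_squared,
    n_scales_used = x$n_scales_used, valid = x$valid, reason = x$reason
  )
}
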