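#' Configuration for a synthetic power-law transect
#'
#' Describes a one-dimensional field whose power spectral density follows
#' \eqn{PSD(k) \propto k^{-\beta}}, sampled at a fixed along-track step,
#' with an optional lognormal marginal (chlorophyll-like), an additive
#' white-noise floor, and injected data gaps. The configuration plus its
#' seed fully determine the generated series (bit-identical output).
#'
#' @param beta Spectral exponent (dimensionless). `beta = 0` is white noise,
#'   `beta = 5/3` the classical inertial-subrange slope, `beta = 2` a
#'   Brownian-like red field.
#' @param n_samples Number of samples in the transect (>= 3).
#' @param dx_km Along-track step in km (default 0.21, the median step of a
#'   sailing-vessel underway system at 1-minute binning).
#' @param marginal `"gaussian"` or `"lognormal"`. The lognormal marginal is
#'   moment-matched: values are `exp(mu + sigma * z)` with `mu`, `sigma`
#'   solved so the field has mean `mean_level` and standard deviation
#'   `amplitude`; this guarantees strictly positive values and makes the
#'   log-transformed field exactly affine in the Gaussian precursor.
#' @param noise_floor Variance of added i.i.d. noise as a fraction of the
#'   signal variance (>= 0). Additive for gaussian marginals; applied on
#'   the log scale (multiplicative) for lognormal marginals so positivity
#'   is preserved.
#' @param gap_fraction Fraction of samples replaced by `NA`, in \[0, 0.5\].
#'   The realized number of gaps is exactly `round(gap_fraction * n_samples)`.
#' @param gap_pattern `"random_single"` (independent single samples) or
#'   `"random_blocks"` (geometric block lengths, mean 10 samples, mimicking
#'   instrument dropouts).
#' @param mean_level,amplitude Target mean and standard deviation of the
#'   field in native units. `amplitude` must be > 0; for a lognormal
#'   marginal `mean_level` must also be > 0.
#' @param oversample Integer >= 1. The Fourier synthesis is carried out on
#'   a circle of `oversample * n_samples` points and a contiguous window of
#'   `n_samples` is returned. With `oversample = 1` the series is exactly
#'   periodic (zero spectral leakage); the default of 4 yields a
#'   non-periodic window, the analogue of a ship transect cutting through a
#'   much larger ocean field. See the methods vignette.
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG stream.
#' @return A list of class `"transect_config"`.
#' @seealso [gen_powerlaw_series()]
#' @export
transect_config <- function(beta,
                            n_samples = 500,
                            dx_km = 0.21,
                            marginal = c("gaussian", "lognormal"),
                            noise_floor = 0,
                            gap_fraction = 0,
                            gap_pattern = c("random_single", "random_blocks"),
                            mean_level = 0,
                            amplitude = 1,
                            oversample = 4,
                            seed = NULL) {
  check_number(beta, "beta")
  n_samples <- check_count(n_samples, "n_samples", min = 3L)
  check_number(dx_km, "dx_km")
  if (dx_km <= 0) stop_config("`dx_km` must be > 0")
  marginal <- match.arg(marginal)
  check_number(noise_floor, "noise_floor")
  if (noise_floor < 0) stop_config("`noise_floor` must be >= 0")
  check_fraction(gap_fraction, "gap_fraction", max = 0.5)
  gap_pattern <- match.arg(gap_pattern)
  check_number(mean_level, "mean_level")
  check_number(amplitude, "amplitude")
  if (amplitude <= 0) stop_config("`amplitude` must be > 0")
  if (marginal == "lognormal" && mean_level <= 0)
    stop_config("`mean_level` must be > 0 for a lognormal marginal")
  oversample <- check_count(oversample, "oversample", min = 1L)
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)

  structure(
    list(beta = beta, n_samples = n_samples, dx_km = dx_km,
         marginal = marginal, noise_floor = noise_floor,
         gap_fraction = gap_fraction, gap_pattern = gap_pattern,
         mean_level = mean_level, amplitude = amplitude,
         oversample = oversample, seed = seed),
    class = "transect_config"
  )
}

#' @export
print.transect_config <- function(x, ...) {
  cat(sprintf(
    "<transect_config> beta=%g n=%d dx=%g km %s mean=%g sd=%g gaps=%g%% (%s)\n",
    x$beta, x$n_samples, x$dx_km, x$marginal, x$mean_level, x$amplitude,
    100 * x$gap_fraction, x$gap_pattern))
  invisible(x)
}

# Standardized Gaussian field with PSD ~ k^-beta via random-phase Fourier
# synthesis on a circle of `oversample * n` points; the first `n` samples
# are returned. The DC amplitude is zero, so the mean is decoupled from the
# spectral shape. Consumes the active RNG stream.
powerlaw_gaussian <- function(beta, n, oversample = 4L) {
  m <- oversample * n
  half <- m %/% 2L
  k <- seq_len(half)
  amp <- k^(-beta / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(length.out = m)
  spec[2:(half + 1L)] <- complex(modulus = amp, argument = phase)
  if (m %% 2L == 0L) {
    # Nyquist bin must be real for a real-valued inverse transform
    spec[half + 1L] <- complex(real = amp[half], imaginary = 0)
    if (half > 1L) spec[m:(m - half + 2L)] <- Conj(spec[2:half])
  } else {
    spec[m:(m - half + 1L)] <- Conj(spec[2:(half + 1L)])
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# Apply marginal transform, noise floor and gaps to a standardized Gaussian
# precursor, per a transect_config. Consumes the active RNG stream.
apply_marginal <- function(z, config) {
  n <- config$n_samples
  if (config$marginal == "gaussian") {
    x <- config$mean_level + config$amplitude * z
    if (config$noise_floor > 0)
      x <- x + stats::rnorm(n, 0, sqrt(config$noise_floor) * config$amplitude)
  } else {
    cv <- config$amplitude / config$mean_level
    sigma <- sqrt(log1p(cv^2))
    mu <- log(config$mean_level) - sigma^2 / 2
    logx <- mu + sigma * z
    if (config$noise_floor > 0)
      logx <- logx + stats::rnorm(n, 0, sqrt(config$noise_floor) * sigma)
    x <- exp(logx)
  }
  gap_idx <- draw_gap_indices(n, config$gap_fraction, config$gap_pattern)
  if (length(gap_idx)) x[gap_idx] <- NA_real_
  x
}

# Indices to blank out. Exactly round(gap_fraction * n) samples are removed
# for either pattern. Block lengths are 1 + Geometric(1/10) (mean 10).
draw_gap_indices <- function(n, gap_fraction, gap_pattern) {
  n_gap <- round(gap_fraction * n)
  if (n_gap == 0L) return(integer(0))
  if (gap_pattern == "random_single") return(sample.int(n, n_gap))
  idx <- integer(0)
  while (length(idx) < n_gap) {
    len <- 1L + stats::rgeom(1L, 1 / 10)
    start <- sample.int(n, 1L)
    block <- start:min(n, start + len - 1L)
    idx <- union(idx, block)
  }
  idx[seq_len(n_gap)]
}

#' Generate a synthetic power-law transect
#'
#' Random-phase Fourier synthesis of a 1D field with power spectral density
#' \eqn{\propto k^{-\beta}}, rescaled to the configured mean and amplitude,
#' optionally transformed to a lognormal marginal, degraded by a white-noise
#' floor, and punctured by data gaps (`NA`).
#'
#' @param config A [transect_config()].
#' @return Numeric vector of length `config$n_samples` with `NA` marking
#'   gaps. Identical config + seed gives bit-identical output.
#' @examples
#' cfg <- transect_config(beta = 5/3, n_samples = 500, seed = 1)
#' x <- gen_powerlaw_series(cfg)
#' leg_gamma(x)
#' @export
gen_powerlaw_series <- function(config) {
  if (!inherits(config, "transect_config"))
    stop_config("`config` must be created by transect_config()")
  with_seed_or_ambient(config$seed, {
    z <- powerlaw_gaussian(config$beta, config$n_samples, config$oversample)
    apply_marginal(z, config)
  })
}
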