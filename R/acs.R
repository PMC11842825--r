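#' Configuration for a raw 4 Hz hyperspectral AC-meter stream
#'
#' Emulates an inline hyperspectral absorption/attenuation meter on a
#' flow-through system: total seawater most of the time, with scheduled
#' periods of 0.2-um filtered seawater (dissolved signal only) used
#' downstream to estimate and subtract the dissolved baseline.
#'
#' The simulated total-seawater signal is dissolved + particulate, where
#' particulate absorption carries a chlorophyll-a Gaussian peak centred at
#' 676 nm over a smooth exponential baseline, and particulate attenuation
#' follows a power law \eqn{c_p(\lambda) \propto \lambda^{-\gamma}} whose
#' exponent is the particle-size proxy gamma. The generator records the
#' per-minute ground truth so processing can be tested for exact recovery.
#'
#' @param duration_min Length of the stream in minutes.
#' @param sample_rate_hz Samples per second (default 4).
#' @param wavelengths Strictly increasing wavelength grid (nm) spanning at
#'   least 410-735 nm.
#' @param chl_profile Per-minute chlorophyll-a (mg m^-3), length
#'   `duration_min` (scalars are recycled).
#' @param gamma_profile Per-minute particle-size exponent (dimensionless).
#' @param cdom_profile Per-minute dissolved absorption at 440 nm (m^-1).
#' @param cp550_profile Per-minute particulate attenuation at 550 nm
#'   (m^-1); default `0.3 * chl_profile + 0.05`.
#' @param filtered_period_min,filtered_cadence_min Filtered-seawater
#'   schedule: the first `filtered_period_min` minutes of every
#'   `filtered_cadence_min` are filtered (defaults 10 and 60: ten minutes
#'   every hour).
#' @param spike_rate Fraction of 4 Hz samples replaced by positive spikes
#'   (bubble-like artefacts affecting the whole spectrum).
#' @param noise_sd Instrument noise standard deviation (m^-1) per 4 Hz
#'   sample and wavelength.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `"acs_config"`.
#' @export
acs_config <- function(duration_min,
                       sample_rate_hz = 4,
                       wavelengths = seq(410, 740, by = 4),
                       chl_profile = 0.25,
                       gamma_profile = 0.9,
                       cdom_profile = 0.02,
                       cp550_profile = NULL,
                       filtered_period_min = 10,
                       filtered_cadence_min = 60,
                       spike_rate = 0,
                       noise_sd = 2e-4,
                       seed = NULL) {
  duration_min <- check_count(duration_min, "duration_min", min = 2L)
  sample_rate_hz <- check_count(sample_rate_hz, "sample_rate_hz", min = 1L)
  if (!is.numeric(wavelengths) || length(wavelengths) < 5L ||
      any(diff(wavelengths) <= 0))
    stop_config("`wavelengths` must be a strictly increasing numeric grid")
  if (min(wavelengths) > 410 || max(wavelengths) < 735)
    stop_config("`wavelengths` must span at least [410, 735] nm")
  rep_min <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, duration_min)
    if (length(x) != duration_min)
      stop_config("`%s` must have length 1 or duration_min", name)
    x
  }
  chl_profile <- rep_min(chl_profile, "chl_profile")
  gamma_profile <- rep_min(gamma_profile, "gamma_profile")
  cdom_profile <- rep_min(cdom_profile, "cdom_profile")
  if (is.null(cp550_profile)) cp550_profile <- 0.3 * chl_profile + 0.05
  cp550_profile <- rep_min(cp550_profile, "cp550_profile")
  filtered_period_min <- check_count(filtered_period_min, "filtered_period_min")
  filtered_cadence_min <- check_count(filtered_cadence_min, "filtered_cadence_min")
  if (filtered_period_min >= filtered_cadence_min)
    stop_config("filtered periods must be shorter than their cadence")
  check_fraction(spike_rate, "spike_rate", max = 0.5)
  check_number(noise_sd, "noise_sd")
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)

  structure(
    list(duration_min = duration_min, sample_rate_hz = sample_rate_hz,
         wavelengths = as.numeric(wavelengths), chl_profile = chl_profile,
         gamma_profile = gamma_profile, cdom_profile = cdom_profile,
         cp550_profile = cp550_profile,
         filtered_period_min = filtered_period_min,
         filtered_cadence_min = filtered_cadence_min,
         spike_rate = spike_rate, noise_sd = noise_sd, seed = seed),
    class = "acs_config"
  )
}

# Per-minute true spectra (matrices duration_min x n_wavelengths).
acs_truth <- function(config) {
  wl <- config$wavelengths
  # dissolved (CDOM-like) absorption, exponential in wavelength
  a_diss <- outer(config$cdom_profile, exp(-0.017 * (wl - 440)))
  # particulate absorption: smooth pigment baseline + 676 nm chl peak
  shape <- 0.05 * exp(-0.011 * (wl - 440)) + 0.0145 * exp(-(wl - 676)^2 / (2 * 9^2))
  ap_part <- outer(config$chl_profile, rep(1, length(wl))) *
    matrix(shape, nrow = config$duration_min, ncol = length(wl), byrow = TRUE)
  # particulate attenuation: power law with per-minute exponent
  cp_part <- config$cp550_profile *
    exp(outer(-config$gamma_profile, log(wl / 550)))
  list(a_diss = a_diss, ap_part = ap_part, cp_part = cp_part)
}

# TRUE for minutes scheduled as filtered seawater (1-based minute index).
filtered_minutes <- function(config) {
  ((seq_len(config$duration_min) - 1L) %% config$filtered_cadence_min) <
    config$filtered_period_min
}

#' Generate a raw 4 Hz AC-meter stream
#'
#' @param config An [acs_config()].
#' @return A list of class `"acs_stream"` with elements `minute` (1-based
#'   minute index per 4 Hz sample), `filtered` (logical per sample),
#'   `wavelengths`, `ap` and `cp` (sample-by-wavelength matrices, m^-1),
#'   and `truth`, a list of per-minute ground-truth matrices (`ap_part`,
#'   `cp_part`, `a_diss`) plus the profiles, for recovery tests. The sample
#'   count is exactly `duration_min * 60 * sample_rate_hz`.
#' @export
gen_acs_stream <- function(config) {
  if (!inherits(config, "acs_config"))
    stop_config("`config` must be created by acs_config()")
  truth <- acs_truth(config)
  filt_min <- filtered_minutes(config)
  per_min <- 60L * config$sample_rate_hz
  n <- config$duration_min * per_min
  minute <- rep(seq_len(config$duration_min), each = per_min)
  nw <- length(config$wavelengths)

  with_seed_or_ambient(config$seed, {
    # filtered samples see the dissolved signal only
    ap_true <- truth$a_diss + truth$ap_part * (!filt_min)
    cp_true <- truth$a_diss + truth$cp_part * (!filt_min)
    ap <- ap_true[minute, , drop = FALSE] +
      matrix(stats::rnorm(n * nw, 0, config$noise_sd), n, nw)
    cp <- cp_true[minute, , drop = FALSE] +
      matrix(stats::rnorm(n * nw, 0, config$noise_sd), n, nw)
    if (config$spike_rate > 0) {
      n_spike <- round(config$spike_rate * n)
      if (n_spike > 0) {
        rows <- sample.int(n, n_spike)
        bump <- stats::runif(n_spike, 0.05, 0.5)
        ap[rows, ] <- ap[rows, ] + bump
        cp[rows, ] <- cp[rows, ] + bump
      }
    }
    structure(
      list(minute = minute, filtered = filt_min[minute],
           wavelengths = config$wavelengths, ap = ap, cp = cp,
           config = config,
           truth = c(truth, list(chl_profile = config$chl_profile,
                                 gamma_profile = config$gamma_profile,
                                 cdom_profile = config$cdom_profile,
                                 cp550_profile = config$cp550_profile,
                                 filtered = filt_min))),
      class = "acs_stream"
    )
  })
}

#' @export
print.acs_stream <- function(x, ...) {
  cat(sprintf(
    "<acs_stream> %d min at %d Hz (%d samples), %d wavelengths [%g-%g nm], %d filtered minutes\n",
    x$config$duration_min, x$config$sample_rate_hz, length(x$minute),
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    sum(x$truth$filtered)))
  invisible(x)
}
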