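#' Chlorophyll-a line height at 676 nm
#'
#' Baseline-subtracted particulate absorption at the chlorophyll-a red
#' absorption peak: the absorption at `peak_nm` minus a linear baseline
#' drawn between `base_left_nm` and `base_right_nm`, all three evaluated by
#' linear interpolation on the wavelength grid. An optical proxy for
#' chlorophyll-a concentration. Exactly invariant to adding any affine
#' function of wavelength to the spectrum.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param ap Particulate absorption spectrum (m^-1), same length.
#' @param peak_nm,base_left_nm,base_right_nm Peak and baseline wavelengths.
#' @return Line height (m^-1), or `NA` if the required band is not covered
#'   or the needed values are missing.
#' @export
chl_line_height <- function(wavelengths, ap,
                            peak_nm = 676, base_left_nm = 650,
                            base_right_nm = 715) {
  vals <- interp_spectrum(wavelengths, ap,
                          c(base_left_nm, peak_nm, base_right_nm))
  if (anyNA(vals)) return(NA_real_)
  frac <- (peak_nm - base_left_nm) / (base_right_nm - base_left_nm)
  baseline <- vals[1] + frac * (vals[3] - vals[1])
  unname(vals[2] - baseline)
}

#' Particle-size exponent gamma of the attenuation spectrum
#'
#' Negated least-squares slope of `log(cp)` versus `log(wavelength)` over
#' the fit range: the exponent of \eqn{c_p(\lambda) \propto
#' \lambda^{-\gamma}}, an optical proxy for mean particle size (larger
#' gamma, smaller particles). The chlorophyll absorption region around
#' 676 nm is excluded from the fit by default because the power-law model
#' assumes a non-absorbing spectral shape. Non-positive attenuation values
#' (possible after baseline subtraction) are excluded from the log-space
#' fit; fewer than `min_points` usable wavelengths gives `NA`. Exactly
#' invariant to scaling `cp` by any positive constant.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param cp Particulate attenuation spectrum (m^-1).
#' @param fit_range_nm Two-element range used for the fit.
#' @param exclude_nm Two-element band excluded from the fit (`NULL` to keep
#'   all wavelengths).
#' @param min_points Minimum usable wavelengths (default 5).
#' @return Dimensionless exponent, or `NA`.
#' @export
particle_size_gamma <- function(wavelengths, cp,
                                fit_range_nm = c(450, 700),
                                exclude_nm = c(660, 690),
                                min_points = 5L) {
  keep <- wavelengths >= fit_range_nm[1] & wavelengths <= fit_range_nm[2] &
    is.finite(cp) & cp > 0
  if (!is.null(exclude_nm))
    keep <- keep & !(wavelengths >= exclude_nm[1] & wavelengths <= exclude_nm[2])
  if (sum(keep) < min_points) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log(wavelengths[keep])), log(cp[keep]))
  -unname(fit$coefficients[2])
}

#' Particulate attenuation at a target wavelength
#'
#' Linear interpolation of the attenuation spectrum at `target_nm`
#' (443 nm by default, a standard blue reference).
#'
#' @inheritParams particle_size_gamma
#' @param target_nm Target wavelength (nm).
#' @return Attenuation (m^-1), or `NA` when the grid does not bracket the
#'   target or the bracketing values are missing.
#' @export
cp_at <- function(wavelengths, cp, target_nm = 443) {
  unname(interp_spectrum(wavelengths, cp, target_nm))
}

# Linear interpolation with NA propagation from the bracketing grid points.
interp_spectrum <- function(wavelengths, values, targets) {
  vapply(targets, function(t0) {
    if (t0 < min(wavelengths) || t0 > max(wavelengths)) return(NA_real_)
    hit <- which(wavelengths == t0)
    if (length(hit)) return(values[hit[1]])
    i <- findInterval(t0, wavelengths)
    v1 <- values[i]; v2 <- values[i + 1L]
    if (!is.finite(v1) || !is.finite(v2)) return(NA_real_)
    v1 + (v2 - v1) * (t0 - wavelengths[i]) / (wavelengths[i + 1L] - wavelengths[i])
  }, numeric(1))
}

#' Derive per-minute optical proxies from particulate spectra
#'
#' Computes the three standard biogeochemical proxies — chlorophyll line
#' height, particle-size exponent gamma, and attenuation at 443 nm — for
#' every minute of a particulate spectra object or a long-form spectra
#' table.
#'
#' @param spectra A `particulate_spectra` object from
#'   [derive_particulate()], or a long data frame with columns `minute`,
#'   `wavelength_nm`, `ap_1_m`, `cp_1_m`.
#' @param ... Passed on to [chl_line_height()], [particle_size_gamma()] and
#'   [cp_at()] (e.g. `peak_nm`, `fit_range_nm`, `target_nm`).
#' @return Tibble with one row per minute: `minute`, `chl_lh`, `gamma_cp`,
#'   `cp443`.
#' @export
derive_proxies <- function(spectra, ...) {
  UseMethod("derive_proxies")
}

#' @export
derive_proxies.particulate_spectra <- function(spectra, ...) {
  dots <- list(...)
  args_for <- function(f) dots[names(dots) %in% names(formals(f))]
  tibble::tibble(
    minute = spectra$minute,
    chl_lh = vapply(seq_along(spectra$minute), function(i) {
      do.call(chl_line_height,
              c(list(spectra$wavelengths, spectra$ap[i, ]), args_for(chl_line_height)))
    }, numeric(1)),
    gamma_cp = vapply(seq_along(spectra$minute), function(i) {
      do.call(particle_size_gamma,
              c(list(spectra$wavelengths, spectra$cp[i, ]), args_for(particle_size_gamma)))
    }, numeric(1)),
    cp443 = vapply(seq_along(spectra$minute), function(i) {
      do.call(cp_at,
              c(list(spectra$wavelengths, spectra$cp[i, ]), args_for(cp_at)))
    }, numeric(1))
  )
}

#' @export
derive_proxies.data.frame <- function(spectra, ...) {
  need <- c("minute", "wavelength_nm", "ap_1_m", "cp_1_m")
  if (!all(need %in% names(spectra)))
    stop_config("long spectra need columns: %s", paste(need, collapse = ", "))
  dots <- list(...)
  args_for <- function(f) dots[names(dots) %in% names(formals(f))]
  spectra |>
    dplyr::arrange(.data$minute, .data$wavelength_nm) |>
    dplyr::group_by(minute = .data$minute) |>
    dplyr::summarise(
      chl_lh = do.call(chl_line_height,
                       c(list(.data$wavelength_nm, .data$ap_1_m), args_for(chl_line_height))),
      gamma_cp = do.call(particle_size_gamma,
                         c(list(.data$wavelength_nm, .data$cp_1_m), args_for(particle_size_gamma))),
      cp443 = do.call(cp_at,
                      c(list(.data$wavelength_nm, .data$cp_1_m), args_for(cp_at))),
      .groups = "drop"
    )
}
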