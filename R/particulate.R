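#' Derive particulate spectra by filtered-seawater baseline subtraction
#'
#' Estimates the dissolved optical baseline from the scheduled
#' filtered-seawater periods and subtracts it from the total-seawater
#' minutes, yielding particulate absorption and attenuation spectra.
#'
#' Each contiguous run of filtered minutes is summarized by its median
#' spectrum (robust to residual spikes) located at the period's mid-time.
#' Between consecutive filtered periods the baseline is either
#' interpolated linearly in time (`method = "linear"`), or made to vary
#' proportionally to the normalized fCDOM signal between the bracketing
#' filtered medians (`method = "fcdom_scaled"`), which tracks real
#' dissolved-matter variability when a CDOM fluorometer with adequate
#' signal-to-noise is available. Total minutes before the first or after
#' the last filtered period take the nearest period's baseline.
#'
#' @param binned An `acs_binned` object from [bin_acs()].
#' @param method `"linear"` or `"fcdom_scaled"`.
#' @param fcdom Per-minute fCDOM series aligned with `binned$minute`
#'   (required for `method = "fcdom_scaled"`).
#' @return A list of class `"particulate_spectra"`: `minute` (total
#'   seawater minutes only), `wavelengths`, minute-by-wavelength matrices
#'   `ap`, `cp` (particulate), `baseline_ap`, `baseline_cp` (the dissolved
#'   estimate), and `total_ap`, `total_cp`. By construction
#'   `baseline + particulate == total` exactly.
#' @export
derive_particulate <- function(binned,
                               method = c("linear", "fcdom_scaled"),
                               fcdom = NULL) {
  method <- match.arg(method)
  if (!inherits(binned, "acs_binned"))
    stop_config("`binned` must come from bin_acs()")
  if (method == "fcdom_scaled") {
    if (is.null(fcdom)) stop_config("`fcdom` is required for method = \"fcdom_scaled\"")
    if (length(fcdom) != length(binned$minute))
      stop_config("`fcdom` must align with binned$minute")
  }

  filt <- binned$filtered
  if (!any(filt)) stop_config("no filtered periods in stream; cannot estimate baseline")
  # contiguous runs of filtered minutes -> periods
  r <- rle(filt)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  periods <- which(r$values)
  if (length(periods) < 2L)
    stop_config("need at least 2 filtered periods to interpolate a baseline")

  nw <- length(binned$wavelengths)
  n_per <- length(periods)
  med_ap <- matrix(NA_real_, n_per, nw)
  med_cp <- matrix(NA_real_, n_per, nw)
  t_mid <- numeric(n_per)
  f_mid <- numeric(n_per)
  for (i in seq_len(n_per)) {
    rows <- starts[periods[i]]:ends[periods[i]]
    med_ap[i, ] <- apply(binned$ap[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    med_cp[i, ] <- apply(binned$cp[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    t_mid[i] <- mean(binned$minute[rows])
    if (method == "fcdom_scaled") f_mid[i] <- stats::median(fcdom[rows], na.rm = TRUE)
  }

  tot <- which(!filt)
  t_tot <- binned$minute[tot]

  baseline_at <- function(med) {
    out <- matrix(NA_real_, length(tot), nw)
    if (method == "linear") {
      for (j in seq_len(nw))
        out[, j] <- stats::approx(t_mid, med[, j], xout = t_tot, rule = 2)$y
      return(out)
    }
    # fcdom_scaled: within each bracketing pair, weight by the normalized
    # fCDOM excursion; degenerate (flat) fCDOM collapses to linear-in-time
    f_tot <- fcdom[tot]
    iv <- findInterval(t_tot, t_mid)
    for (idx in seq_along(t_tot)) {
      i <- iv[idx]
      if (i == 0L) { out[idx, ] <- med[1L, ]; next }           # before first period
      if (i >= n_per) { out[idx, ] <- med[n_per, ]; next }     # after last period
      df <- f_mid[i + 1L] - f_mid[i]
      w <- if (abs(df) > .Machine$double.eps^0.5) {
        (f_tot[idx] - f_mid[i]) / df
      } else {
        (t_tot[idx] - t_mid[i]) / (t_mid[i + 1L] - t_mid[i])
      }
      out[idx, ] <- med[i, ] + w * (med[i + 1L, ] - med[i, ])
    }
    out
  }

  base_ap <- baseline_at(med_ap)
  base_cp <- baseline_at(med_cp)
  total_ap <- binned$ap[tot, , drop = FALSE]
  total_cp <- binned$cp[tot, , drop = FALSE]

  structure(
    list(minute = t_tot, wavelengths = binned$wavelengths,
         ap = total_ap - base_ap, cp = total_cp - base_cp,
         baseline_ap = base_ap, baseline_cp = base_cp,
         total_ap = total_ap, total_cp = total_cp),
    class = "particulate_spectra"
  )
}
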