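#' Percentile-trimmed mean and standard deviation
#'
#' Core of the minute-binning step: samples strictly outside the 2.5th to
#' 97.5th percentile interval (linear-interpolation quantiles; boundary
#' values retained) are dropped, which removes bubble spikes from
#' flow-through optical records. Returns the mean of the retained samples,
#' their standard deviation as an uncertainty estimate, and the retained
#' count.
#'
#' @param x Numeric samples (one minute's worth); `NA` ignored.
#' @param lower,upper Trim percentiles as fractions (defaults 0.025, 0.975).
#' @return Named numeric vector `c(mean, sd, n_used)`; all `NA`/empty input
#'   gives `c(NA, NA, 0)`.
#' @export
trimmed_stats <- function(x, lower = 0.025, upper = 0.975) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_, n_used = 0))
  q <- stats::quantile(x, c(lower, upper), names = FALSE, type = 7)
  keep <- x >= q[1] & x <= q[2]
  v <- x[keep]
  c(mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else 0,
    n_used = length(v))
}

#' Bin a 4 Hz scalar record to per-minute values
#'
#' Groups raw samples by minute and applies the percentile-trimmed mean
#' ([trimmed_stats()]) within each group. Minutes with no samples yield
#' `NA` means, not errors.
#'
#' @param data Data frame of raw samples.
#' @param value Column holding the measured quantity (tidy-eval).
#' @param minute Column holding the minute label (tidy-eval, default
#'   `minute`).
#' @param lower,upper Trim percentiles passed to [trimmed_stats()].
#' @return Tibble with one row per minute: `minute`, `mean`, `sd`, `n_used`.
#' @examples
#' raw <- tibble::tibble(minute = rep(1:2, each = 240),
#'                       v = c(rnorm(240), rnorm(240, 5)))
#' minute_bin(raw, v)
#' @export
minute_bin <- function(data, value, minute = minute,
                       lower = 0.025, upper = 0.975) {
  data |>
    dplyr::group_by(minute = {{ minute }}) |>
    dplyr::summarise(
      stats = list(trimmed_stats({{ value }}, lower, upper)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("stats")
}

#' Bin a raw AC-meter stream to per-minute spectra
#'
#' Applies the percentile trim independently per minute and wavelength to
#' both absorption and attenuation channels.
#'
#' @param stream An `acs_stream` from [gen_acs_stream()] (or any list with
#'   `minute`, `filtered`, `wavelengths`, `ap`, `cp`).
#' @param lower,upper Trim percentiles.
#' @return A list of class `"acs_binned"`: `minute` (1-based, one entry per
#'   observed minute), `filtered` (logical per minute), `wavelengths`, and
#'   minute-by-wavelength matrices `ap`, `cp`, `ap_sd`, `cp_sd`, `n_used`.
#' @export
bin_acs <- function(stream, lower = 0.025, upper = 0.975) {
  minutes <- sort(unique(stream$minute))
  nw <- length(stream$wavelengths)
  bin_one <- function(mat) {
    out_m <- matrix(NA_real_, length(minutes), nw)
    out_s <- matrix(NA_real_, length(minutes), nw)
    out_n <- matrix(0, length(minutes), nw)
    for (i in seq_along(minutes)) {
      rows <- which(stream$minute == minutes[i])
      for (j in seq_len(nw)) {
        st <- trimmed_stats(mat[rows, j], lower, upper)
        out_m[i, j] <- st[["mean"]]; out_s[i, j] <- st[["sd"]]
        out_n[i, j] <- st[["n_used"]]
      }
    }
    list(mean = out_m, sd = out_s, n = out_n)
  }
  ap <- bin_one(stream$ap)
  cp <- bin_one(stream$cp)
  filt <- vapply(minutes, function(m) {
    any(stream$filtered[stream$minute == m])
  }, logical(1))
  structure(
    list(minute = minutes, filtered = filt,
         wavelengths = stream$wavelengths,
         ap = ap$mean, cp = cp$mean, ap_sd = ap$sd, cp_sd = cp$sd,
         n_used = pmin(ap$n, cp$n)),
    class = "acs_binned"
  )
}
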