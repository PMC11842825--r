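#' Default per-variable transect configurations for an underway stream
#'
#' Study-condition defaults for the seven standard underway variables.
#' Physical tracers (temperature, salinity, density) are red, Gaussian
#' fields with spectral exponent 2 (variance slope near 1); biogeochemical
#' tracers (chlorophyll, particulate attenuation) are lognormal with
#' exponent 1.5 (variance slope near 0.5) and a within-leg coefficient of
#' variation of 0.3, typical of open-ocean 100-km legs. fCDOM sits between
#' the two groups. See the methods vignette for the rationale.
#'
#' @param n_samples Number of per-minute samples shared by all variables.
#' @return Named list of [transect_config()] objects with the standard
#'   column names (`temp_c`, `sal_psu`, `sigma_kg_m3`, `chl_mg_m3`,
#'   `cp443_1_m`, `gamma_cp`, `fcdom_au`).
#' @export
default_variable_configs <- function(n_samples = 500) {
  list(
    temp_c      = transect_config(2.0, n_samples, mean_level = 18,    amplitude = 1.5),
    sal_psu     = transect_config(2.0, n_samples, mean_level = 35,    amplitude = 0.5),
    sigma_kg_m3 = transect_config(2.0, n_samples, mean_level = 1025,  amplitude = 0.5),
    chl_mg_m3   = transect_config(1.5, n_samples, marginal = "lognormal",
                                  mean_level = 0.25, amplitude = 0.075),
    cp443_1_m   = transect_config(1.5, n_samples, marginal = "lognormal",
                                  mean_level = 0.10, amplitude = 0.03),
    gamma_cp    = transect_config(1.5, n_samples, mean_level = 0.9,   amplitude = 0.15),
    fcdom_au    = transect_config(1.8, n_samples, mean_level = 1.0,   amplitude = 0.2)
  )
}

#' Generate a synthetic multivariable underway stream
#'
#' Assembles one per-minute georeferenced record per track position, with
#' each variable drawn from its own power-law configuration. Cross-variable
#' correlation between the absolute values of named pairs is imposed by
#' Gaussian-copula mixing of the precursors before the marginal transforms,
#' so the realized correlation after a lognormal transform is approximate
#' (within about 0.1 of the target).
#'
#' @param track A [track_config()] (or a track tibble from [gen_track()]).
#' @param var_configs Named list of [transect_config()], one per variable
#'   column; all must share `n_samples` with the track. Defaults to
#'   [default_variable_configs()].
#' @param cross_corr Optional data frame with columns `var_a`, `var_b`, `r`
#'   giving target Pearson correlations between variable pairs. Pairs are
#'   applied in order; each mixes `var_b`'s precursor towards `var_a`'s.
#' @param seed Integer seed for the whole stream, or `NULL`. Per-variable
#'   seeds inside `var_configs` take precedence for their own variable.
#' @return Tibble (the underway stream): `time`, `lat`, `lon`, plus one
#'   column per variable with `NA` marking gaps.
#' @examples
#' trk <- track_config(500, seed = 1)
#' stream <- gen_underway_stream(trk, seed = 1)
#' dplyr::glimpse(stream)
#' @export
gen_underway_stream <- function(track,
                                var_configs = NULL,
                                cross_corr = NULL,
                                seed = NULL) {
  if (inherits(track, "track_config")) {
    n <- track$n_samples
    track_tbl <- gen_track(track)
  } else if (is.data.frame(track)) {
    if (!all(c("time", "lat", "lon") %in% names(track)))
      stop_config("a track data frame needs `time`, `lat`, `lon` columns")
    n <- nrow(track)
    track_tbl <- tibble::as_tibble(track[c("time", "lat", "lon")])
  } else {
    stop_config("`track` must be a track_config() or a track data frame")
  }
  if (is.null(var_configs)) var_configs <- default_variable_configs(n)
  if (is.null(names(var_configs)) || any(names(var_configs) == ""))
    stop_config("`var_configs` must be a named list")
  for (nm in names(var_configs)) {
    cfg <- var_configs[[nm]]
    if (!inherits(cfg, "transect_config"))
      stop_config("`var_configs$%s` is not a transect_config()", nm)
    if (cfg$n_samples != n)
      stop_config("`var_configs$%s` has n_samples = %d but the track has %d",
                  nm, cfg$n_samples, n)
  }
  if (!is.null(cross_corr)) {
    cross_corr <- as.data.frame(cross_corr)
    need <- c("var_a", "var_b", "r")
    if (!all(need %in% names(cross_corr)))
      stop_config("`cross_corr` needs columns var_a, var_b, r")
    bad <- setdiff(unique(c(cross_corr$var_a, cross_corr$var_b)),
                   names(var_configs))
    if (length(bad))
      stop_config("cross_corr names not in var_configs: %s",
                  paste(bad, collapse = ", "))
    if (any(abs(cross_corr$r) >= 1))
      stop_config("cross_corr targets must be in (-1, 1)")
  }

  cols <- with_seed_or_ambient(seed, {
    # Gaussian precursors, one per variable
    z <- purrr::map(var_configs, function(cfg) {
      with_seed_or_ambient(cfg$seed,
        powerlaw_gaussian(cfg$beta, n, cfg$oversample))
    })
    # copula mixing on the precursors, then re-standardize
    if (!is.null(cross_corr)) {
      for (i in seq_len(nrow(cross_corr))) {
        a <- cross_corr$var_a[i]; b <- cross_corr$var_b[i]
        r <- cross_corr$r[i]
        zb <- r * z[[a]] + sqrt(1 - r^2) * z[[b]]
        z[[b]] <- (zb - mean(zb)) / stats::sd(zb)
      }
    }
    # marginal transform, noise floor and gaps draw from the stream-level
    # RNG stream; per-variable seeds pin the spectral precursor only
    purrr::imap(z, function(zi, nm) apply_marginal(zi, var_configs[[nm]]))
  })

  dplyr::bind_cols(track_tbl, tibble::as_tibble(cols))
}
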