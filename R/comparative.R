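#' Correlation between the variance slopes of two variables
#'
#' Pairwise-complete correlation of per-leg variance slopes: the test of
#' whether two properties share spatial organization. Physical variables
#' correlate with each other, biogeochemical variables correlate with each
#' other, and the two groups do not — the central comparative result this
#' layer exists for.
#'
#' @param table A [gamma_table()] (long: `leg_id`, `variable`, `gamma`,
#'   `valid`).
#' @param var_a,var_b Variable names to correlate.
#' @param method `"pearson"` (default; the R^2 convention) or
#'   `"spearman"`.
#' @return One-row tibble: `var_a`, `var_b`, `method`, `r`, `r_squared`,
#'   `p_value` (two-sided), `n` (legs with valid slopes for both).
#' @export
correlate_gammas <- function(table, var_a, var_b,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wide <- gamma_pairs(table, var_a, var_b)
  if (nrow(wide) < 3L)
    stop_config("need >= 3 legs with valid slopes for both variables, got %d",
                nrow(wide))
  ct <- stats::cor.test(wide[[var_a]], wide[[var_b]], method = method,
                        exact = FALSE)
  tibble::tibble(
    var_a = var_a, var_b = var_b, method = method,
    r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value, n = nrow(wide)
  )
}

# valid slopes of two variables, one row per leg holding both
gamma_pairs <- function(table, var_a, var_b) {
  need <- c("leg_id", "variable", "gamma", "valid")
  if (!all(need %in% names(table)))
    stop_config("`table` must have columns: %s", paste(need, collapse = ", "))
  missing_vars <- setdiff(c(var_a, var_b), unique(table$variable))
  if (length(missing_vars))
    stop_config("variables not in table: %s", paste(missing_vars, collapse = ", "))
  table |>
    dplyr::filter(.data$variable %in% c(var_a, var_b), .data$valid) |>
    dplyr::select("leg_id", "variable", "gamma") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "gamma") |>
    tidyr::drop_na()
}

#' Variance slope restricted to small scales
#'
#' Recomputes the variance slope using only windows up to
#' `max_window_samples` — e.g. 25 samples (about 5 km at a 0.21 km step)
#' instead of the full 500 (about 100 km) — to ask whether a comparative
#' result depends on the top-end length scale.
#'
#' @inheritParams scale_variance
#' @inheritParams fit_gamma
#' @param max_window_samples Largest window retained.
#' @return A `"variance_slope_fit"`.
#' @export
scale_restricted_gamma <- function(x, max_window_samples,
                                   scheme = window_scheme(),
                                   min_block_coverage = 0.8,
                                   var_method = c("sample", "population"),
                                   weight_by_blocks = FALSE) {
  sizes <- scheme[scheme <= max_window_samples]
  if (length(sizes) < 2L)
    stop_config("fewer than 2 window sizes at or below %d samples",
                max_window_samples)
  leg_gamma(x, structure(as.integer(sizes), class = c("window_scheme", "integer")),
            min_block_coverage, var_method, weight_by_blocks = weight_by_blocks)
}

#' Aggregate per-leg variance slopes by biogeochemical province
#'
#' Unweighted per-province means of the variance slope and of the absolute
#' value, per variable, for provinces containing at least `min_legs` legs.
#' Provinces are any regional partition supplied as a leg-to-label mapping
#' (typically Longhurst biogeochemical provinces; the point-in-polygon
#' assignment itself is upstream of this package). Optionally joins a
#' user-supplied table of province covariates (e.g. climatological
#' nutrients and oxygen saturation).
#'
#' @param table A [gamma_table()].
#' @param leg_to_province Data frame with columns `leg_id`, `province`.
#'   Legs absent from the mapping are dropped with a warning.
#' @param min_legs Minimum number of distinct legs for a province to be
#'   retained (default 25).
#' @param covariates Optional data frame keyed by `province`, joined to
#'   the output.
#' @return Tibble with one row per (province, variable): `province`,
#'   `variable`, `n_legs` (distinct legs in the province), `mean_gamma`,
#'   `mean_abs_value`, plus any covariate columns.
#' @export
province_aggregate <- function(table, leg_to_province, min_legs = 25,
                               covariates = NULL) {
  if (!all(c("leg_id", "province") %in% names(leg_to_province)) ||
      nrow(as.data.frame(leg_to_province)) == 0L)
    stop_config("`leg_to_province` must be a non-empty table with `leg_id`, `province`")
  mapped <- dplyr::inner_join(table, tibble::as_tibble(leg_to_province),
                              by = "leg_id")
  n_dropped <- length(setdiff(unique(table$leg_id), unique(mapped$leg_id)))
  if (n_dropped > 0L)
    warning(sprintf("%d legs had no province mapping and were dropped", n_dropped),
            call. = FALSE)
  out <- mapped |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$province) |>
    dplyr::mutate(n_legs = dplyr::n_distinct(.data$leg_id)) |>
    dplyr::group_by(.data$province, .data$variable, .data$n_legs) |>
    dplyr::summarise(
      mean_gamma = mean(.data$gamma),
      mean_abs_value = mean(.data$mean_abs_value),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_legs >= min_legs) |>
    dplyr::relocate("province", "variable", "n_legs")
  if (!is.null(covariates)) {
    if (!"province" %in% names(covariates))
      stop_config("`covariates` must be keyed by a `province` column")
    out <- dplyr::left_join(out, tibble::as_tibble(covariates), by = "province")
  }
  out
}

#' Relation between variance slope and absolute magnitude
#'
#' Pearson correlation between a variable's per-leg mean absolute value
#' and its variance slope. For concentration-dependent biological
#' variables the relation is positive (high-biomass legs are less patchy);
#' physical variables show none.
#'
#' @param table A [gamma_table()].
#' @param variable Variable name.
#' @return One-row tibble: `variable`, `r`, `r_squared`, `slope_sign`,
#'   `p_value`, `n`.
#' @export
gamma_vs_magnitude <- function(table, variable) {
  rows <- table |>
    dplyr::filter(.data$variable == !!variable, .data$valid) |>
    tidyr::drop_na("gamma", "mean_abs_value")
  if (nrow(rows) < 3L)
    stop_config("need >= 3 valid legs for `%s`, got %d", variable, nrow(rows))
  if (stats::sd(rows$mean_abs_value) < .Machine$double.eps^0.5)
    stop_config("absolute values of `%s` are constant; correlation undefined",
                variable)
  ct <- stats::cor.test(rows$mean_abs_value, rows$gamma)
  tibble::tibble(
    variable = variable, r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    slope_sign = sign(unname(ct$estimate)),
    p_value = ct$p.value, n = nrow(rows)
  )
}

#' Binned spatial autocorrelogram of the variance slope
#'
#' Moran-style correlogram: all leg pairs are binned by the haversine
#' distance between leg centroids, and within each bin the Pearson
#' correlation of the paired slope values (both orientations of each pair)
#' is reported. Distinguishes spatially organized patchiness (high
#' short-lag correlation) from geographically random patchiness.
#'
#' @param table A [gamma_table()].
#' @param variable Variable name.
#' @param lag_edges_km Optional vector of bin edges (km); by default
#'   `n_bins` logarithmic bins spanning the observed pair distances.
#' @param n_bins Number of logarithmic bins when `lag_edges_km` is `NULL`.
#' @param min_pairs Bins with fewer pairs are flagged (default 10).
#' @return Tibble of class `"gamma_correlogram"`: `lag_min_km`,
#'   `lag_max_km`, `lag_mid_km`, `r`, `n_pairs`, `flagged`.
#' @export
spatial_autocorrelogram <- function(table, variable, lag_edges_km = NULL,
                                    n_bins = 10, min_pairs = 10) {
  rows <- table |>
    dplyr::filter(.data$variable == !!variable, .data$valid) |>
    tidyr::drop_na("gamma", "centroid_lat", "centroid_lon")
  if (nrow(rows) < 10L)
    stop_config("need >= 10 legs with centroids, got %d", nrow(rows))
  n <- nrow(rows)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- haversine_km(rows$centroid_lat[ij[, 1]], rows$centroid_lon[ij[, 1]],
                    rows$centroid_lat[ij[, 2]], rows$centroid_lon[ij[, 2]])
  if (is.null(lag_edges_km)) {
    dmin <- max(min(d[d > 0]), 1e-3)
    lag_edges_km <- exp(seq(log(dmin * 0.999), log(max(d) * 1.001),
                            length.out = n_bins + 1L))
  }
  bin <- cut(d, lag_edges_km, labels = FALSE, include.lowest = TRUE)
  if (all(is.na(bin))) stop_config("no leg pairs fall inside the lag bins")
  g1 <- rows$gamma[ij[, 1]]; g2 <- rows$gamma[ij[, 2]]
  out <- purrr::map_dfr(seq_len(length(lag_edges_km) - 1L), function(b) {
    sel <- which(!is.na(bin) & bin == b)
    r <- if (length(sel) >= 2L) {
      # both orientations: the symmetric (Moran-style) pair correlation
      stats::cor(c(g1[sel], g2[sel]), c(g2[sel], g1[sel]))
    } else NA_real_
    tibble::tibble(
      lag_min_km = lag_edges_km[b], lag_max_km = lag_edges_km[b + 1L],
      lag_mid_km = sqrt(lag_edges_km[b] * lag_edges_km[b + 1L]),
      r = r, n_pairs = length(sel), flagged = length(sel) < min_pairs
    )
  })
  tibble::new_tibble(out, class = "gamma_correlogram")
}
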