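#' Per-leg variance slopes for a set of variables
#'
#' Runs [leg_gamma()] on every (leg, variable) combination of a segmented
#' stream and assembles the long table that feeds all comparative
#' statistics: one row per leg and variable with the fitted variance
#' slope, fit diagnostics, the leg's mean absolute value of the variable,
#' and the leg centroid.
#'
#' @param legs Leg table from [segment_legs()] (must carry the `data` list
#'   column).
#' @param variables Character vector of variable columns; defaults to every
#'   variable with a `coverage_` column in `legs`.
#' @inheritParams scale_variance
#' @inheritParams fit_gamma
#' @return Tibble with columns `leg_id`, `variable`, `gamma`, `intercept`,
#'   `r_squared`, `n_scales_used`, `valid`, `reason`, `mean_abs_value`,
#'   `coverage`, `centroid_lat`, `centroid_lon`.
#' @examples
#' stream <- gen_underway_stream(track_config(1000, seed = 2), seed = 2)
#' legs <- segment_legs(stream)
#' gamma_table(legs, c("temp_c", "chl_mg_m3"))
#' @export
gamma_table <- function(legs, variables = NULL,
                        scheme = window_scheme(),
                        min_block_coverage = 0.8,
                        var_method = c("sample", "population"),
                        weight_by_blocks = FALSE) {
  var_method <- match.arg(var_method)
  if (!"data" %in% names(legs))
    stop_config("`legs` must carry the `data` list column from segment_legs()")
  if (is.null(variables)) {
    variables <- sub("^coverage_", "", grep("^coverage_", names(legs), value = TRUE))
    if (!length(variables)) stop_config("no variables found in `legs`")
  }
  purrr::map_dfr(seq_len(nrow(legs)), function(i) {
    rows <- legs$data[[i]]
    purrr::map_dfr(variables, function(v) {
      if (!v %in% names(rows)) stop_config("variable `%s` not in leg data", v)
      x <- rows[[v]]
      fit <- if (all(is.na(x))) NULL else {
        leg_gamma(x, scheme, min_block_coverage, var_method,
                  weight_by_blocks = weight_by_blocks)
      }
      tibble::tibble(
        leg_id = legs$leg_id[i],
        variable = v,
        gamma = if (is.null(fit)) NA_real_ else fit$gamma,
        intercept = if (is.null(fit)) NA_real_ else fit$intercept,
        r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
        n_scales_used = if (is.null(fit)) 0L else fit$n_scales_used,
        valid = if (is.null(fit)) FALSE else fit$valid,
        reason = if (is.null(fit)) "all_missing" else fit$reason,
        mean_abs_value = mean(abs(x), na.rm = TRUE),
        coverage = mean(!is.na(x)),
        centroid_lat = legs$centroid_lat[i],
        centroid_lon = legs$centroid_lon[i]
      )
    })
  })
}
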