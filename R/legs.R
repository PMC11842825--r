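#' Quality-control criteria for transect legs
#'
#' Defaults follow the conservative screening used for basin-scale underway
#' analyses: a leg must travel between 30 and 150 km along track, carry
#' valid data in at least 80% of its slots, and span no more than 16 hours
#' of wall clock (a sailing vessel may drift or stop, stretching 500
#' nominal minutes of records over much longer).
#'
#' @param min_distance_km,max_distance_km Allowed along-track (path)
#'   distance range, km.
#' @param min_coverage Minimum valid-data fraction in (0, 1].
#' @param max_elapsed_hours Maximum elapsed wall-clock time, hours.
#' @return A list of class `"qc_criteria"`.
#' @export
qc_criteria <- function(min_distance_km = 30,
                        max_distance_km = 150,
                        min_coverage = 0.80,
                        max_elapsed_hours = 16) {
  check_number(min_distance_km, "min_distance_km")
  check_number(max_distance_km, "max_distance_km")
  if (min_distance_km >= max_distance_km)
    stop_config("`min_distance_km` must be < `max_distance_km`")
  check_fraction(min_coverage, "min_coverage")
  if (min_coverage <= 0) stop_config("`min_coverage` must be in (0, 1]")
  check_number(max_elapsed_hours, "max_elapsed_hours")
  structure(
    list(min_distance_km = min_distance_km,
         max_distance_km = max_distance_km,
         min_coverage = min_coverage,
         max_elapsed_hours = max_elapsed_hours),
    class = "qc_criteria"
  )
}

#' Segment an underway stream into fixed-size legs
#'
#' Cuts the stream into consecutive, non-overlapping legs of `leg_size`
#' rows in time order; a trailing remainder shorter than `leg_size` is
#' discarded. The stream is nominally one record per minute: small
#' instrument gaps appear as `NA` cells within existing rows (they count
#' against per-variable coverage), while minutes wholly absent from the
#' table stretch a leg's elapsed time (caught downstream by the 16-hour
#' quality rule).
#'
#' @param stream Underway stream: a data frame with `time`, `lat`, `lon`
#'   and one column per measured variable.
#' @param leg_size Rows per leg (default 500, roughly 100 km at a 0.21 km
#'   median step).
#' @param variables Variable columns for which to compute coverage;
#'   defaults to every column other than `time`/`lat`/`lon`.
#' @return Tibble with one row per leg: `leg_id`, `start_time`,
#'   `elapsed_hours` (last minus first timestamp), `along_track_km` (sum of
#'   haversine steps between consecutive valid positions), `median_step_km`,
#'   `centroid_lat`, `centroid_lon`, one `coverage_<variable>` column per
#'   variable (valid fraction of `leg_size`), and `data`, a list column
#'   holding each leg's rows. A stream shorter than `leg_size` gives an
#'   empty tibble.
#' @export
segment_legs <- function(stream, leg_size = 500, variables = NULL) {
  if (!is.data.frame(stream) || !all(c("time", "lat", "lon") %in% names(stream)))
    stop_config("`stream` must have `time`, `lat`, `lon` columns")
  leg_size <- check_count(leg_size, "leg_size", min = 2L)
  if (is.null(variables))
    variables <- setdiff(names(stream), c("time", "lat", "lon"))
  missing_vars <- setdiff(variables, names(stream))
  if (length(missing_vars))
    stop_config("variables not in stream: %s", paste(missing_vars, collapse = ", "))

  stream <- dplyr::arrange(tibble::as_tibble(stream), .data$time)
  n_legs <- nrow(stream) %/% leg_size
  if (n_legs == 0L) return(empty_leg_table(variables))

  purrr::map_dfr(seq_len(n_legs), function(i) {
    rows <- stream[((i - 1L) * leg_size + 1L):(i * leg_size), ]
    ok_pos <- !is.na(rows$lat) & !is.na(rows$lon)
    pos <- rows[ok_pos, c("lat", "lon")]
    steps <- if (nrow(pos) > 1L) {
      haversine_km(pos$lat[-nrow(pos)], pos$lon[-nrow(pos)],
                   pos$lat[-1L], pos$lon[-1L])
    } else numeric(0)
    cov <- purrr::map_dbl(variables, ~ mean(!is.na(rows[[.x]])))
    names(cov) <- paste0("coverage_", variables)
    out <- tibble::tibble(
      leg_id = i,
      start_time = rows$time[1L],
      elapsed_hours = as.numeric(difftime(rows$time[leg_size], rows$time[1L],
                                          units = "hours")),
      along_track_km = sum(steps),
      median_step_km = if (length(steps)) stats::median(steps) else NA_real_,
      centroid_lat = mean(rows$lat, na.rm = TRUE),
      centroid_lon = mean(rows$lon, na.rm = TRUE)
    )
    dplyr::bind_cols(out, tibble::as_tibble_row(cov),
                     tibble::tibble(data = list(rows)))
  })
}

empty_leg_table <- function(variables) {
  out <- tibble::tibble(
    leg_id = integer(0),
    start_time = as.POSIXct(character(0), tz = "UTC"),
    elapsed_hours = numeric(0), along_track_km = numeric(0),
    median_step_km = numeric(0),
    centroid_lat = numeric(0), centroid_lon = numeric(0)
  )
  for (v in variables) out[[paste0("coverage_", v)]] <- numeric(0)
  out$data <- list()
  out
}

#' Quality-filter transect legs
#'
#' Applies the leg-level quality rules for a chosen variable: along-track
#' distance within \[30, 150\] km, coverage of that variable at least 80%,
#' and elapsed time at most 16 hours (all configurable via
#' [qc_criteria()]). Every failed rule is recorded, so the returned table
#' documents why each leg was rejected.
#'
#' @param legs Leg table from [segment_legs()] (any data frame with
#'   `along_track_km`, `elapsed_hours` and a `coverage_<variable>` column).
#' @param variable Variable whose coverage is tested.
#' @param criteria A [qc_criteria()].
#' @return The leg table with two added columns: `qc_pass` (logical) and
#'   `qc_reason` (comma-separated codes among `distance_short`,
#'   `distance_long`, `coverage`, `elapsed`; `NA` for passing legs).
#'   Filter with `dplyr::filter(qc_pass)` to keep the survivors.
#' @export
qc_filter <- function(legs, variable, criteria = qc_criteria()) {
  if (!inherits(criteria, "qc_criteria"))
    stop_config("`criteria` must come from qc_criteria()")
  cov_col <- paste0("coverage_", variable)
  if (!cov_col %in% names(legs))
    stop_config("unknown variable `%s`: no `%s` column in legs", variable, cov_col)
  reasons <- purrr::pmap_chr(
    list(legs$along_track_km, legs[[cov_col]], legs$elapsed_hours),
    function(d, cov, eh) {
      r <- character(0)
      if (is.na(d) || d < criteria$min_distance_km) r <- c(r, "distance_short")
      else if (d > criteria$max_distance_km) r <- c(r, "distance_long")
      if (is.na(cov) || cov < criteria$min_coverage) r <- c(r, "coverage")
      if (is.na(eh) || eh > criteria$max_elapsed_hours) r <- c(r, "elapsed")
      if (length(r)) paste(r, collapse = ",") else NA_character_
    }
  )
  legs |>
    dplyr::mutate(qc_pass = is.na(reasons), qc_reason = reasons)
}
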