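# Earth radius (km) used for every great-circle distance in the package.
EARTH_RADIUS_KM <- 6371.0

#' Haversine distance between points, in kilometres
#'
#' Thin wrapper around [geosphere::distHaversine()] pinned to a 6371 km
#' Earth radius so that every distance in the package is computed with the
#' same convention.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Vectors are
#'   recycled by `geosphere`.
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Run `expr` under `seed` when non-NULL, otherwise with the ambient RNG
# stream (so callers can drive everything from one set.seed()).
with_seed_or_ambient <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# shared argument checks ------------------------------------------------

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    stop_config("`%s` must be a single finite number", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name)
  if (x != round(x) || x < min)
    stop_config("`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, max = 1) {
  check_number(x, name)
  if (x < 0 || x > max)
    stop_config("`%s` must be in [0, %s]", name, format(max))
  x
}
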