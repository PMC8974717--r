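# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

EARTH_RADIUS_KM <- 6378.137

#' Convert calendar dates to 1-based day-of-year
#'
#' @param date a `Date` vector (or something coercible by [as.Date()]).
#' @return integer day-of-year, 1 = January 1st. Leap years give Dec 31 = 366.
#' @export
date_to_doy <- function(date) {
  date <- as.Date(date)
  as.integer(format(date, "%j"))
}

#' Convert day-of-year back to a calendar date
#'
#' @param doy integer day-of-year (1-based).
#' @param year calendar year.
#' @return a `Date` vector.
#' @export
doy_to_date <- function(doy, year) {
  as.Date(doy - 1L, origin = as.Date(paste0(year, "-01-01")))
}

# great-circle distance in km between (lat1,lon1) and (lat2,lon2)
dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

# great-circle central angle in degrees (used for circle membership,
# whose radius is expressed in degrees)
dist_deg <- function(lon1, lat1, lon2, lat2) {
  dist_km(lon1, lat1, lon2, lat2) / (pi * EARTH_RADIUS_KM / 180)
}

# initial bearing (degrees from north) from point 1 toward point 2
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  (b + 360) %% 360
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
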