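# Core domain containers: daily pollen series, phenological observation
# tables and back trajectories. All are lightweight S3 objects (lists or
# data frames) with strict constructors, so every downstream module can
# assume validated inputs.

#' Construct a daily pollen series
#'
#' One station-by-taxon-by-year vector of daily airborne pollen
#' concentrations (pollen grains m^-3). Missing days are `NA` in `conc`;
#' days before trap start simply have no entry.
#'
#' @param station_id character station identifier.
#' @param taxon pollen taxon name (e.g. `"Betula"`).
#' @param year calendar year of the series.
#' @param doy integer day-of-year vector, strictly increasing, within 1..366.
#' @param conc numeric concentration per day, `NA` for missing, otherwise
#'   non-negative (pollen grains m^-3).
#' @param first_operation_doy day the trap started operating; defaults to the
#'   first day carried by the series. Must not exceed the first day with a
#'   present value.
#' @return an object of class `daily_pollen_series`: a list with the fields
#'   above plus `conc` and `doy` aligned.
#' @examples
#' s <- daily_pollen_series("E", "Betula", 2010, doy = 100:104,
#'                          conc = c(0, 2, NA, 5, 1))
#' s$conc
#' @export
daily_pollen_series <- function(station_id, taxon, year, doy, conc,
                                first_operation_doy = NULL) {
  doy <- as.integer(doy)
  conc <- as.numeric(conc)
  if (length(doy) != length(conc))
    stop("`doy` and `conc` must have equal length", call. = FALSE)
  if (length(doy) == 0L) stop("empty series", call. = FALSE)
  if (any(doy < 1L | doy > 366L))
    stop("day-of-year out of range 1..366", call. = FALSE)
  if (any(diff(doy) <= 0L))
    stop("`doy` must be strictly increasing", call. = FALSE)
  if (any(conc < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed", call. = FALSE)
  first_present <- suppressWarnings(min(doy[!is.na(conc)]))
  first_operation_doy <- as.integer(first_operation_doy %||% min(doy))
  if (is.finite(first_present) && first_operation_doy > first_present)
    stop("`first_operation_doy` exceeds the first day with a present value",
         call. = FALSE)
  structure(
    list(station_id = as.character(station_id), taxon = as.character(taxon),
         year = as.integer(year), first_operation_doy = first_operation_doy,
         doy = doy, conc = conc),
    class = "daily_pollen_series")
}

#' @export
print.daily_pollen_series <- function(x, ...) {
  cat(sprintf("<daily_pollen_series> %s / %s / %d\n",
              x$station_id, x$taxon, x$year))
  cat(sprintf("  %d days (doy %d..%d), %d missing, trap start doy %d\n",
              length(x$doy), min(x$doy), max(x$doy), sum(is.na(x$conc)),
              x$first_operation_doy))
  invisible(x)
}

#' Validate a table of phenological observations
#'
#' Checks a data frame of flowering-onset observations (one row per
#' site-by-species-by-year) for the columns and ranges the interpolation
#' model requires.
#'
#' @param df data frame with columns `site_id`, `lat`, `lon`, `elevation_m`,
#'   `species`, `year`, `onset_doy`.
#' @return the validated data frame (invisibly unchanged), with class
#'   `pheno_observations` prepended.
#' @export
as_pheno_observations <- function(df) {
  need <- c("site_id", "lat", "lon", "elevation_m", "species", "year",
            "onset_doy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing phenology columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$elevation_m)))
    stop("missing or non-finite elevation; the regional regression needs it",
         call. = FALSE)
  if (any(df$lat < -90 | df$lat > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(df$lon < -180 | df$lon > 180))
    stop("longitude out of range [-180, 180]", call. = FALSE)
  if (any(df$onset_doy < 1 | df$onset_doy > 366))
    stop("onset day-of-year out of range 1..366", call. = FALSE)
  key <- paste(df$site_id, df$species, df$year)
  if (anyDuplicated(key))
    stop("duplicate site/species/year rows: ",
         key[which(duplicated(key))[1L]], call. = FALSE)
  class(df) <- unique(c("pheno_observations", class(df)))
  df
}

#' Construct a back trajectory
#'
#' A 72 h backward air-parcel path arriving at a receptor. Point ages are
#' non-positive hours (0 at arrival, decreasing backward in time).
#'
#' @param start_time `POSIXct` (or coercible) arrival time at the receptor.
#' @param start_lat,start_lon arrival coordinates (decimal degrees).
#' @param start_altitude_m starting height above ground (m); runs in this
#'   package default to 500 m.
#' @param points data frame with columns `age_hours` (0, -3, ...), `lat`,
#'   `lon`, `altitude_m`, ordered by decreasing age.
#' @return an object of class `trajectory`; a `flags` character vector notes
#'   points older than the 72 h window.
#' @export
trajectory <- function(start_time, start_lat, start_lon,
                       start_altitude_m = 500, points) {
  need <- c("age_hours", "lat", "lon", "altitude_m")
  miss <- setdiff(need, names(points))
  if (length(miss))
    stop("trajectory points lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(points) == 0L) stop("trajectory has no points", call. = FALSE)
  if (any(points$age_hours > 0))
    stop("back-trajectory point ages must be non-positive", call. = FALSE)
  if (any(diff(points$age_hours) >= 0))
    stop("point ages must strictly decrease (backward in time)",
         call. = FALSE)
  if (abs(points$lat[1L] - start_lat) > 1e-4 ||
      abs(points$lon[1L] - start_lon) > 1e-4)
    stop("first trajectory point must coincide with the start location",
         call. = FALSE)
  flags <- character(0)
  if (any(points$age_hours < -72)) flags <- c(flags, "BEYOND_72H")
  structure(
    list(start_time = as.POSIXct(start_time, tz = "UTC"),
         start_lat = start_lat, start_lon = start_lon,
         start_altitude_m = start_altitude_m,
         points = as.data.frame(points), flags = flags),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> start %s at (%.3f, %.3f) %gm AGL, %d points\n",
              format(x$start_time, "%Y-%m-%d %H:%M"), x$start_lat,
              x$start_lon, x$start_altitude_m, nrow(x$points)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
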