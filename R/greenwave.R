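# Green-wave extrapolation of flowering dates along back-trajectory
# footprints and the three-day confirmation rule for hypothesized
# pre-season transport.
#
# The "green wave" is the directional progression of spring phenology
# across Europe: early spring moves from WSW toward ENE, mid and late
# spring from SW toward NE and SSW toward NNE, summer roughly south to
# north. A location up-wave of the receptor (in the direction the wave
# comes from) flowers earlier by (projected distance) / (wave speed).

#' Construct a seasonal green-wave model
#'
#' @param segments data frame with columns `start_doy`, `end_doy` (half-open
#'   windows `[start, end)`, jointly covering days 1..366 without overlap),
#'   `bearing_deg` (direction the wave moves toward, degrees from north) and
#'   `speed_km_day` (> 0).
#' @return the validated data frame with class `green_wave_model`.
#' @export
green_wave_model <- function(segments) {
  need <- c("start_doy", "end_doy", "bearing_deg", "speed_km_day")
  stopifnot(all(need %in% names(segments)))
  seg <- segments[order(segments$start_doy), , drop = FALSE]
  if (seg$start_doy[1L] != 1L || seg$end_doy[nrow(seg)] != 367L)
    stop("segments must cover day-of-year 1..366", call. = FALSE)
  if (nrow(seg) > 1L &&
      any(seg$start_doy[-1L] != seg$end_doy[-nrow(seg)]))
    stop("segment windows must tile 1..366 without gaps or overlap",
         call. = FALSE)
  if (any(seg$speed_km_day <= 0))
    stop("wave speeds must be positive", call. = FALSE)
  class(seg) <- unique(c("green_wave_model", class(seg)))
  seg
}

#' Default green-wave configuration
#'
#' Seasonal bearings follow the documented progression (ENE in early
#' spring, NE then NNE through spring, N in summer). The shipped speeds are
#' placeholders of plausible literature order (tens of km per day); any
#' quantitative reproduction must set speeds explicitly from the scheme
#' being reproduced.
#'
#' @param speeds_km_day numeric length-4 vector of segment speeds
#'   (early spring, mid spring, late spring, summer).
#' @return a `green_wave_model`.
#' @export
default_green_wave <- function(speeds_km_day = c(30, 35, 40, 45)) {
  stopifnot(length(speeds_km_day) == 4L)
  green_wave_model(data.frame(
    start_doy = c(1L, 91L, 136L, 167L),
    end_doy = c(91L, 136L, 167L, 367L),
    bearing_deg = c(67.5, 45, 22.5, 0),   # toward ENE, NE, NNE, N
    speed_km_day = speeds_km_day,
    segment = c("early_spring", "mid_spring", "late_spring", "summer")))
}

#' Wave segment in effect on a given day
#'
#' @param model a `green_wave_model`.
#' @param doy day-of-year in 1..366. A day on a window boundary belongs to
#'   the later (starting) window, windows being half-open `[start, end)`.
#' @return the single matching segment row.
#' @export
wave_segment_for_doy <- function(model, doy) {
  stopifnot(doy >= 1, doy <= 366)
  hit <- which(model$start_doy <= doy & doy < model$end_doy)
  stopifnot(length(hit) == 1L)
  model[hit, , drop = FALSE]
}

#' Extrapolate a flowering date along the green wave
#'
#' Projects the great-circle displacement from a trajectory point to the
#' receptor onto the wave's propagation bearing and converts the projected
#' distance to days at the wave speed:
#' `SOS_T(point) = SOS_F(receptor) - projection_km / speed`. Points up-wave
#' of the receptor flower earlier, down-wave later; displacement
#' perpendicular to the bearing leaves the date unchanged. The segment is
#' chosen by the receptor's flowering day.
#'
#' @param point_lat,point_lon trajectory point (decimal degrees);
#'   vectorised.
#' @param receptor_lat,receptor_lon receptor station coordinates.
#' @param receptor_sos_f receptor flowering start (day-of-year).
#' @param model a `green_wave_model`.
#' @return extrapolated flowering day-of-year (numeric, unrounded).
#' @export
extrapolate_sos_t <- function(point_lat, point_lon, receptor_lat,
                              receptor_lon, receptor_sos_f,
                              model = default_green_wave()) {
  seg <- wave_segment_for_doy(model, receptor_sos_f)
  d <- dist_km(point_lon, point_lat, receptor_lon, receptor_lat)
  # bearing measured at the receptor, where the wave bearing is defined;
  # the point->receptor projection is then -d*cos(bearing - wave bearing),
  # which is exactly antisymmetric in the displacement sign
  b <- bearing_deg(receptor_lon, receptor_lat, point_lon, point_lat)
  proj <- ifelse(d == 0, 0, -d * cos((b - seg$bearing_deg) * pi / 180))
  receptor_sos_f - proj / seg$speed_km_day
}

#' Earliest extrapolated flowering date under a day's trajectories
#'
#' The minimum of [extrapolate_sos_t()] over every endpoint of every
#' trajectory arriving that day (typically the eight 3-hourly starts). The
#' age-0 arrival endpoint coincides with the receptor and carries no
#' upstream information, so it is excluded by default; a footprint that is
#' entirely local (all upstream points at the receptor) still evaluates to
#' the receptor's flowering date.
#'
#' @param trajectories list of [trajectory()] objects for one day.
#' @param receptor_lat,receptor_lon,receptor_sos_f as in
#'   [extrapolate_sos_t()].
#' @param model a `green_wave_model`.
#' @param exclude_arrival drop the age-0 endpoint of each trajectory
#'   (default TRUE; ignored when a trajectory has no older points).
#' @return day-of-year (numeric): the earliest flowering anywhere under the
#'   footprint.
#' @export
earliest_sos_t <- function(trajectories, receptor_lat, receptor_lon,
                           receptor_sos_f, model = default_green_wave(),
                           exclude_arrival = TRUE) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  if (!length(trajectories)) stop("no trajectories", call. = FALSE)
  vals <- unlist(lapply(trajectories, function(tr) {
    pts <- tr$points
    if (exclude_arrival && any(pts$age_hours < 0))
      pts <- pts[pts$age_hours < 0, , drop = FALSE]
    extrapolate_sos_t(pts$lat, pts$lon, receptor_lat, receptor_lon,
                      receptor_sos_f, model)
  }))
  min(vals)
}

#' Assess a transport hypothesis from three days of trajectories
#'
#' Per-day likelihood of transport: `high` when the earliest upstream
#' flowering date is at or before the pollen start (`SOS_T <= SOS_P`),
#' `medium` when it is after the pollen start but at or before local
#' flowering (`SOS_P < SOS_T <= SOS_F`), `zero` otherwise. The hypothesis
#' is `CONFIRMED` if at least one of the three days (season start and the
#' two days before) is high, `PARTLY_CONFIRMED` if none is high but at
#' least one is medium, else `REJECTED`.
#'
#' @param sos_t_days numeric, up to 3 per-day earliest flowering dates
#'   (day of SOS_P, one day and two days prior); `NA` for days with no
#'   trajectory data (excluded).
#' @param sos_p,sos_f pollen and flowering season starts (day-of-year).
#' @return list of class `transport_assessment`: `per_day` (character
#'   likelihoods) and `overall`.
#' @export
assess_transport <- function(sos_t_days, sos_p, sos_f) {
  if (length(sos_t_days) < 1L || length(sos_t_days) > 3L)
    stop("expected 1..3 per-day SOS_T values", call. = FALSE)
  ok <- is.finite(sos_t_days)
  if (!any(ok)) stop("no trajectory day available", call. = FALSE)
  lik <- rep(NA_character_, length(sos_t_days))
  lik[ok] <- ifelse(sos_t_days[ok] <= sos_p, "high",
                    ifelse(sos_t_days[ok] <= sos_f, "medium", "zero"))
  overall <- if (any(lik == "high", na.rm = TRUE)) "CONFIRMED"
  else if (any(lik == "medium", na.rm = TRUE)) "PARTLY_CONFIRMED"
  else "REJECTED"
  # internal consistency of the rule set
  if (overall == "REJECTED")
    stopifnot(all(sos_t_days[ok] > sos_f))
  structure(list(per_day = lik, overall = overall, sos_p = sos_p,
                 sos_f = sos_f), class = "transport_assessment")
}

#' @export
print.transport_assessment <- function(x, ...) {
  cat(sprintf("<transport_assessment> %s (per day: %s)\n", x$overall,
              paste(ifelse(is.na(x$per_day), "-", x$per_day),
                    collapse = ", ")))
  invisible(x)
}
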