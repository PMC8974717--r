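# Synthetic inputs with known ground truth: pollen years, phenology
# networks, trajectories, and fully labelled end-to-end transport
# scenarios. Every generator is seed-deterministic and returns its truth
# record alongside the data, so every pipeline stage is testable without
# access to the restricted monitoring archives.

#' Simulate one station/taxon/year of daily pollen concentrations
#'
#' The seasonal curve is Gaussian in time (any unimodal shape exercises the
#' season definition; the Gaussian gives closed-form truth quantiles), with
#' optional truncated-at-zero Gaussian day-to-day noise, missing-day
#' spells, and an optional pre-season transport pulse. Truth season
#' parameters are the 2.5% cumulative quantiles of the noise-free curve
#' (before any pulse).
#'
#' @param center,width peak day-of-year and Gaussian width (days) of the
#'   season curve.
#' @param amplitude peak daily concentration (grains m^-3).
#' @param noise_sd sd of additive Gaussian noise, truncated at zero.
#' @param missing_spells list of `c(start_doy, length)` runs set missing.
#' @param pulse optional `list(day =, magnitude =, width =)` pre-season
#'   pulse (its own small Gaussian bump).
#' @param doy_range days carried by the series (default 1..366).
#' @param station_id,taxon,year labels for the series.
#' @param seed RNG seed (integer); the generator is fully deterministic
#'   given the seed.
#' @return list with `series` (a [daily_pollen_series()]) and `truth`
#'   (`sos`, `peak`, `eos`, `sum` of the noise-free pulse-free curve, plus
#'   the pulse day if any).
#' @export
simulate_pollen_year <- function(center = 110, width = 10, amplitude = 50,
                                 noise_sd = 0, missing_spells = list(),
                                 pulse = NULL, doy_range = c(1L, 365L),
                                 station_id = "SYN", taxon = "Betula",
                                 year = 2010L, seed = 1L) {
  stopifnot(width > 0, amplitude > 0)
  set.seed(seed)
  doy <- seq.int(doy_range[1L], doy_range[2L])
  curve <- amplitude * exp(-0.5 * ((doy - center) / width)^2)
  cs <- cumsum(curve)
  truth <- list(
    sos = doy[which(cs >= 0.025 * sum(curve))[1L]],
    peak = doy[which.max(curve)],
    eos = doy[which(cs >= 0.975 * sum(curve))[1L]],
    sum = sum(curve))
  conc <- curve
  if (!is.null(pulse)) {
    pw <- pulse$width %||% 2
    conc <- conc + pulse$magnitude * exp(-0.5 * ((doy - pulse$day) / pw)^2)
    truth$pulse_day <- pulse$day
  }
  if (noise_sd > 0)
    conc <- pmax(0, conc + stats::rnorm(length(doy), 0, noise_sd))
  conc[conc < 1e-6] <- 0
  for (sp in missing_spells) {
    idx <- which(doy >= sp[1L] & doy < sp[1L] + sp[2L])
    conc[idx] <- NA_real_
  }
  list(series = daily_pollen_series(station_id, taxon, year, doy, conc),
       truth = truth)
}

#' Simulate a phenological observation network
#'
#' Sites are placed uniformly in a coordinate/elevation box; onset dates
#' follow the regional regression `DOY = a0 + a1*h + a2*lon + a3*lat` plus
#' Gaussian noise, rounded to integer days as real observations are. A
#' linear trend on `a0` across years can be imposed to give the trend
#' machinery a known slope.
#'
#' @param coef numeric length-4 truth coefficients `c(a0, a1, a2, a3)`.
#' @param n_sites number of sites.
#' @param lat_range,lon_range,elev_range uniform placement ranges.
#' @param noise_sd observation noise sd (days).
#' @param round_days round onsets to whole days as real observations are
#'   reported (default TRUE); FALSE keeps exact dates for recovery tests.
#' @param years integer vector of years (default a single year 2010).
#' @param trend_a0 change of `a0` per year (days yr^-1, default 0).
#' @param species label for the observations.
#' @param seed RNG seed.
#' @return list with `obs` (a `pheno_observations` data frame across all
#'   years, site locations shared) and `truth` (`coef`, `trend_a0`).
#' @export
simulate_pheno_network <- function(coef = c(60, 0.03, -2, 4), n_sites = 50,
                                   lat_range = c(47.3, 50.5),
                                   lon_range = c(9, 13.8),
                                   elev_range = c(200, 1200),
                                   noise_sd = 0, round_days = TRUE,
                                   years = 2010L, trend_a0 = 0,
                                   species = "Betula", seed = 1L) {
  stopifnot(length(coef) == 4L, n_sites >= 4L, noise_sd >= 0)
  set.seed(seed)
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    lat = stats::runif(n_sites, lat_range[1L], lat_range[2L]),
    lon = stats::runif(n_sites, lon_range[1L], lon_range[2L]),
    elevation_m = stats::runif(n_sites, elev_range[1L], elev_range[2L]))
  obs <- do.call(rbind, lapply(years, function(yr) {
    a0 <- coef[1L] + trend_a0 * (yr - years[1L])
    mu <- a0 + coef[2L] * sites$elevation_m + coef[3L] * sites$lon +
      coef[4L] * sites$lat
    doy <- mu + stats::rnorm(n_sites, 0, noise_sd)
    if (round_days) doy <- round(doy)
    cbind(sites, data.frame(species = species, year = as.integer(yr),
                            onset_doy = pmin(pmax(doy, 1), 366)))
  }))
  list(obs = as_pheno_observations(obs),
       truth = list(coef = coef, trend_a0 = trend_a0))
}

#' Simulate one day of back trajectories toward an origin
#'
#' Eight trajectories start 3-hourly at the receptor; endpoints drift along
#' the great circle toward `origin_bearing_deg`, reaching `distance_km` at
#' age -72 h (25 points at 3 h resolution), with optional positional
#' jitter. Optionally also written in the HYSPLIT endpoint layout for
#' parser round-trips.
#'
#' @param receptor_lat,receptor_lon receptor coordinates.
#' @param origin_bearing_deg bearing from the receptor toward the air-mass
#'   origin (degrees from north).
#' @param distance_km origin distance at the 72 h horizon (0 keeps all
#'   points at the receptor).
#' @param date arrival `Date` of the trajectory day.
#' @param n_per_day trajectory starts per day (default 8, i.e. 3-hourly).
#' @param jitter_km sd of kilometre-scale scatter added to each endpoint.
#' @param start_altitude_m starting height (default 500 m AGL).
#' @param tdump_path if non-NULL, the set is also written there via
#'   [write_tdump()].
#' @param seed RNG seed (used by the jitter only).
#' @return list of [trajectory()] objects.
#' @export
simulate_trajectories <- function(receptor_lat, receptor_lon,
                                  origin_bearing_deg, distance_km,
                                  date = as.Date("2010-04-01"),
                                  n_per_day = 8L, jitter_km = 0,
                                  start_altitude_m = 500,
                                  tdump_path = NULL, seed = 1L) {
  stopifnot(distance_km >= 0)
  set.seed(seed)
  ages <- seq(0, -72, by = -3)
  hours <- seq(0, by = 24 / n_per_day, length.out = n_per_day)
  trajs <- lapply(hours, function(h) {
    frac <- abs(ages) / 72
    if (distance_km > 0) {
      p <- geosphere::destPoint(c(receptor_lon, receptor_lat),
                                origin_bearing_deg,
                                frac * distance_km * 1000,
                                r = EARTH_RADIUS_KM * 1000)
    } else {
      p <- cbind(lon = rep(receptor_lon, length(ages)),
                 lat = rep(receptor_lat, length(ages)))
    }
    lon <- p[, 1L]; lat <- p[, 2L]
    if (jitter_km > 0) {
      keep <- frac > 0   # arrival point stays exactly at the receptor
      lat[keep] <- lat[keep] +
        stats::rnorm(sum(keep), 0, jitter_km / 111.2)
      lon[keep] <- lon[keep] +
        stats::rnorm(sum(keep), 0, jitter_km / 111.2)
    }
    trajectory(
      start_time = as.POSIXct(date, tz = "UTC") + h * 3600,
      start_lat = receptor_lat, start_lon = receptor_lon,
      start_altitude_m = start_altitude_m,
      points = data.frame(age_hours = ages, lat = lat, lon = lon,
                          altitude_m = start_altitude_m))
  })
  if (!is.null(tdump_path)) write_tdump(trajs, tdump_path)
  trajs
}

#' Build a fully labelled end-to-end transport scenario
#'
#' Generates a consistent bundle — pollen year, local flowering date,
#' three days of trajectories — whose pipeline output is known by
#' construction: `"local"` cases have pollen starting within the local
#' window of flowering, `"preseason_transport"` cases start well before
#' flowering with up-wave trajectories, `"faulty"` cases start well after
#' flowering. Transport scenarios use an origin far enough up-wave that
#' the extrapolated flowering lead covers the pollen lead; local and
#' faulty scenarios get down-wave trajectories (no upstream earlier
#' flowering).
#'
#' @param label one of `"local"`, `"preseason_transport"`, `"faulty"`.
#' @param seed RNG seed; varies the season geometry between scenarios.
#' @param flowering_noise_sd sd (days) added to the reported flowering
#'   date.
#' @param pollen_shift_sd sd (days) of a whole-series shift of the pollen
#'   year (jitters SOS_P).
#' @param model green-wave model used to size the transport geometry.
#' @return list with `label`, `series`, `sos_f` (reported flowering
#'   day-of-year), `receptor` (`lat`, `lon`), `trajectories` (list of 3
#'   days, each a list of trajectories), `truth`, and `expected`
#'   (`source_class`, `overall` for transport cases else `REJECTED`).
#' @export
build_transport_scenario <- function(label = c("local",
                                               "preseason_transport",
                                               "faulty"),
                                     seed = 1L, flowering_noise_sd = 0,
                                     pollen_shift_sd = 0,
                                     model = default_green_wave()) {
  label <- match.arg(label)
  set.seed(seed)
  receptor <- list(lat = 48.1, lon = 11.6)
  sos_f_true <- round(stats::runif(1, 105, 125))
  target_diff <- switch(label, local = 0, preseason_transport = -25,
                        faulty = 25)
  width <- stats::runif(1, 8, 12)
  dshift <- if (pollen_shift_sd > 0)
    round(stats::rnorm(1, 0, pollen_shift_sd)) else 0L
  fshift <- if (flowering_noise_sd > 0)
    round(stats::rnorm(1, 0, flowering_noise_sd)) else 0L
  # place the curve so its truth SOS lands on sos_f + target_diff (then
  # jitter the whole season by dshift days when pollen noise is requested)
  probe <- simulate_pollen_year(center = 150, width = width,
                                noise_sd = 0, seed = seed)
  shift <- (sos_f_true + target_diff) - probe$truth$sos
  pol <- simulate_pollen_year(center = 150 + shift + dshift, width = width,
                              noise_sd = 0, seed = seed)
  sos_f <- sos_f_true + fshift
  seg <- wave_segment_for_doy(model, sos_f_true)
  up_bearing <- (seg$bearing_deg + 180) %% 360
  dist <- switch(label,
                 preseason_transport =
                   (abs(target_diff) + 10) * seg$speed_km_day,
                 local = 300, faulty = 300)
  bearing <- if (label == "preseason_transport") up_bearing else
    seg$bearing_deg   # down-wave for non-transport scenarios
  days <- pol$truth$sos - (0:2)
  trajectories <- lapply(seq_along(days), function(i)
    simulate_trajectories(receptor$lat, receptor$lon, bearing, dist,
                          date = doy_to_date(days[i], pol$series$year),
                          seed = seed + i))
  # the trajectory assessment is only meaningful when pollen precedes
  # flowering; a faulty case is screened out before it, so no label there
  expected <- list(
    source_class = switch(label, local = "LOCAL",
                          preseason_transport = "PRE_SEASON_TRANSPORT",
                          faulty = "NO_LOCAL_OR_FAULTY"),
    overall = switch(label, preseason_transport = "CONFIRMED",
                     local = "REJECTED", faulty = NA_character_))
  list(label = label, series = pol$series, sos_f = sos_f,
       receptor = receptor, trajectories = trajectories,
       truth = pol$truth, expected = expected)
}

#' Run the classification pipeline on a scenario bundle
#'
#' Convenience wrapper used in end-to-end recovery tests: imputes, defines
#' the season, classifies the case against the bundled flowering date and,
#' for the three bundled trajectory days, assesses the transport
#' hypothesis.
#'
#' @param scenario output of [build_transport_scenario()].
#' @param alpha percentage-method trim level.
#' @param model green-wave model for the assessment.
#' @return list with `season`, `diff`, `source_class` and `assessment`.
#' @export
run_transport_scenario <- function(scenario, alpha = 2.5,
                                   model = default_green_wave()) {
  season <- define_season_percentage(impute_lineal(scenario$series),
                                     alpha = alpha)
  diff <- season$sos_p - scenario$sos_f
  source_class <- classify_case(diff, "lowland")
  sos_t <- vapply(scenario$trajectories, earliest_sos_t,
                  numeric(1), receptor_lat = scenario$receptor$lat,
                  receptor_lon = scenario$receptor$lon,
                  receptor_sos_f = scenario$sos_f, model = model)
  list(season = season, diff = diff, source_class = source_class,
       assessment = assess_transport(sos_t, season$sos_p, scenario$sos_f))
}
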