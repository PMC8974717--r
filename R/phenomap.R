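# Spatial interpolation of flowering onset dates: regional multiple linear
# regressions of onset day-of-year on elevation, longitude and latitude
# fitted inside overlapping circles, inverse-distance interpolation of the
# circle coefficients, prediction on a pixel grid, and per-pixel trend
# distributions across years.

#' Lay out overlapping regression circles over a phenology network
#'
#' Places circle centres on a regular lattice over the bounding box of the
#' observations, sized to produce approximately `n_circles` circles. The
#' operational German scheme uses 30 overlapping circles of 1.95 degrees;
#' both numbers are configuration here.
#'
#' @param obs `pheno_observations` data frame (only `lat`/`lon` are used).
#' @param n_circles approximate number of circles (default 30).
#' @param radius_deg circle radius as a great-circle angle in degrees
#'   (default 1.95).
#' @return data frame with columns `center_lat`, `center_lon`, `radius_deg`.
#' @export
make_circles <- function(obs, n_circles = 30, radius_deg = 1.95) {
  stopifnot(radius_deg > 0)
  lat_r <- range(obs$lat); lon_r <- range(obs$lon)
  aspect <- max(diff(lon_r), 1e-6) / max(diff(lat_r), 1e-6)
  n_lat <- max(1L, round(sqrt(n_circles / aspect)))
  n_lon <- max(1L, ceiling(n_circles / n_lat))
  grid <- expand.grid(
    center_lat = seq(lat_r[1L], lat_r[2L], length.out = n_lat),
    center_lon = seq(lon_r[1L], lon_r[2L], length.out = n_lon))
  grid$radius_deg <- radius_deg
  grid
}

#' Fit the regional onset regression within one circle
#'
#' Ordinary least squares of onset day-of-year on elevation (m), longitude
#' and latitude (degrees) over the observations lying within the circle
#' (great-circle membership, radius in degrees):
#' `DOY = a0 + a1*h + a2*lon + a3*lat`.
#'
#' @param obs `pheno_observations` data frame (one species, one year).
#' @param circle one row of [make_circles()] output (or any list with
#'   `center_lat`, `center_lon`, `radius_deg`).
#' @param min_n minimum member observations for a usable fit (default 10).
#' @return list of class `circle_model` with `circle`, coefficients `a0`
#'   (days), `a1` (days m^-1), `a2`/`a3` (days per degree), `n_obs`, `rmse`
#'   (days); or `NULL` (skip marker) when under-populated or rank deficient.
#' @export
fit_circle_model <- function(obs, circle, min_n = 10) {
  d <- dist_deg(obs$lon, obs$lat, circle$center_lon, circle$center_lat)
  m <- obs[d <= circle$radius_deg, , drop = FALSE]
  if (nrow(m) < max(min_n, 4L)) return(NULL)
  X <- cbind(1, m$elevation_m, m$lon, m$lat)
  if (qr(X)$rank < 4L) return(NULL)
  fit <- stats::lm.fit(X, m$onset_doy)
  structure(
    list(circle = circle, a0 = fit$coefficients[1L],
         a1 = fit$coefficients[2L], a2 = fit$coefficients[3L],
         a3 = fit$coefficients[4L], n_obs = nrow(m),
         rmse = sqrt(mean(fit$residuals^2))),
    class = "circle_model")
}

#' Interpolate circle coefficients to a target point
#'
#' Inverse-distance weighting of each regression coefficient independently
#' over the `k` nearest circle centres, with `k` between `k_min` and `k_max`
#' (the operational scheme uses the nearest two to four). A target that
#' coincides with a centre returns that circle's coefficients.
#'
#' @param models list of `circle_model`s (skip markers removed or `NULL`s
#'   tolerated).
#' @param lat,lon target point (decimal degrees).
#' @param k_min,k_max number of contributing circles (defaults 2 and 4).
#' @param power IDW exponent (default 2); distances are great-circle km
#'   between circle centres and the target.
#' @return named numeric vector `c(a0, a1, a2, a3)`.
#' @export
interpolate_coefficients <- function(models, lat, lon, k_min = 2, k_max = 4,
                                     power = 2) {
  models <- Filter(Negate(is.null), models)
  if (length(models) < k_min)
    stop(sprintf("coverage error: %d fitted circle(s), need at least %d",
                 length(models), k_min), call. = FALSE)
  centers <- t(vapply(models, function(m)
    c(m$circle$center_lon, m$circle$center_lat), numeric(2)))
  d <- dist_km(centers[, 1L], centers[, 2L], lon, lat)
  k <- min(k_max, length(models))
  near <- order(d)[seq_len(k)]
  coefs <- t(vapply(models[near], function(m) c(a0 = unname(m$a0),
                                                a1 = unname(m$a1),
                                                a2 = unname(m$a2),
                                                a3 = unname(m$a3)),
                    numeric(4)))
  dn <- d[near]
  if (any(dn == 0)) return(coefs[which(dn == 0)[1L], ])
  w <- 1 / dn^power
  w <- w / sum(w)
  colSums(coefs * w)
}

#' Predict flowering onset on a pixel grid
#'
#' For every grid pixel, interpolates the circle coefficients to the pixel
#' and evaluates the onset regression on the pixel's elevation, longitude
#' and latitude. Pixels outside the coverage of every fitted circle get no
#' prediction (counted in the returned `n_uncovered`).
#'
#' @param models list of `circle_model`s.
#' @param grid data frame of pixels with columns `lat`, `lon`,
#'   `elevation_m`; typically a regular lattice approximating 1 km^2 cells.
#' @param species,year labels carried to the output.
#' @param ... passed to [interpolate_coefficients()].
#' @return object of class `flowering_surface`: list with `species`, `year`,
#'   `pixels` (the grid plus `sos_f` — unrounded prediction — and
#'   `sos_f_day`, the integer day for reporting) and `n_uncovered`.
#' @export
predict_doy_grid <- function(models, grid, species = NA_character_,
                             year = NA_integer_, ...) {
  stopifnot(all(c("lat", "lon", "elevation_m") %in% names(grid)))
  models <- Filter(Negate(is.null), models)
  if (!length(models)) stop("no fitted circle models", call. = FALSE)
  covered <- rep(FALSE, nrow(grid))
  for (m in models) {
    covered <- covered |
      dist_deg(grid$lon, grid$lat, m$circle$center_lon,
               m$circle$center_lat) <= m$circle$radius_deg
  }
  sos_f <- rep(NA_real_, nrow(grid))
  for (i in which(covered)) {
    a <- interpolate_coefficients(models, grid$lat[i], grid$lon[i], ...)
    sos_f[i] <- a[1L] + a[2L] * grid$elevation_m[i] + a[3L] * grid$lon[i] +
      a[4L] * grid$lat[i]
  }
  px <- grid
  px$sos_f <- sos_f
  px$sos_f_day <- as.integer(round(sos_f))
  structure(list(species = species, year = year, pixels = px,
                 n_uncovered = sum(!covered)),
            class = "flowering_surface")
}

#' @export
print.flowering_surface <- function(x, ...) {
  cat(sprintf("<flowering_surface> %s / %s: %d pixels (%d uncovered)\n",
              x$species, x$year, nrow(x$pixels), x$n_uncovered))
  invisible(x)
}

#' Flowering onset at a station's pixel
#'
#' Returns the interpolated onset of the pixel containing the station.
#' Pixels are half-open cells centred on the grid nodes; a station on a cell
#' boundary belongs to the lower-left cell (lower lat/lon inclusive).
#'
#' @param surface a `flowering_surface`.
#' @param lat,lon station coordinates.
#' @param rounded return the integer reporting day (default TRUE) or the
#'   unrounded prediction.
#' @return day-of-year (numeric).
#' @export
extract_site_sosf <- function(surface, lat, lon, rounded = TRUE) {
  px <- surface$pixels
  grid_step <- function(v) {
    d <- diff(sort(unique(v)))
    if (!length(d)) 1 else min(d)
  }
  lat_step <- grid_step(px$lat)
  lon_step <- grid_step(px$lon)
  in_cell <- lat >= px$lat - lat_step / 2 & lat < px$lat + lat_step / 2 &
    lon >= px$lon - lon_step / 2 & lon < px$lon + lon_step / 2
  hit <- which(in_cell)
  if (!length(hit))
    stop("station outside the covered grid", call. = FALSE)
  i <- hit[1L]
  if (is.na(px$sos_f[i]))
    stop("station pixel has no prediction (outside circle coverage)",
         call. = FALSE)
  if (rounded) px$sos_f_day[i] else px$sos_f[i]
}

#' Distribution of per-pixel onset trends across years
#'
#' Fits [linear_trend()] at every pixel across a set of annual surfaces and
#' summarises the slope distribution, mirroring a violin-plot comparison of
#' station trends against the landscape-wide flowering trend.
#'
#' @param surfaces list of `flowering_surface`s (one per year, identical
#'   grids).
#' @param years numeric years matching `surfaces`; defaults to the surfaces'
#'   `year` fields.
#' @return list of class `pixel_trend_distribution`: `slopes` (per pixel,
#'   days yr^-1), `quantiles` (2.5/25/50/75/97.5%), and
#'   `contains(station_slope)` — TRUE when the slope lies inside the central
#'   95% of the pixel distribution.
#' @export
pixel_trend_distribution <- function(surfaces, years = NULL) {
  if (length(surfaces) < 3L)
    stop("at least 3 annual surfaces required", call. = FALSE)
  years <- years %||% vapply(surfaces, function(s) as.numeric(s$year),
                             numeric(1))
  grids <- lapply(surfaces, function(s) s$pixels[, c("lat", "lon")])
  for (g in grids[-1L])
    if (!isTRUE(all.equal(g, grids[[1L]], check.attributes = FALSE)))
      stop("surfaces use inconsistent grids", call. = FALSE)
  mat <- vapply(surfaces, function(s) s$pixels$sos_f,
                numeric(nrow(surfaces[[1L]]$pixels)))
  slopes <- apply(mat, 1L, function(v) {
    if (sum(is.finite(v)) < 3L) return(NA_real_)
    linear_trend(years, v)$slope
  })
  qs <- stats::quantile(slopes, c(0.025, 0.25, 0.5, 0.75, 0.975),
                        na.rm = TRUE, names = TRUE)
  structure(
    list(slopes = slopes, quantiles = qs,
         contains = function(station_slope)
           station_slope >= qs[[1L]] & station_slope <= qs[[5L]]),
    class = "pixel_trend_distribution")
}
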