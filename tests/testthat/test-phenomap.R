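# Circle regressions, coefficient interpolation, grid prediction and
# pixel-trend distributions.

big_circle <- function(lat = 48.9, lon = 11.4, r = 10)
  list(center_lat = lat, center_lon = lon, radius_deg = r)

test_that("circle fits recover exact coefficients and skip thin circles", {
  truth <- c(60, 0.03, -2, 4)
  # unrounded observations: exact recovery
  set.seed(1)
  obs <- data.frame(site_id = sprintf("S%02d", 1:40),
                    lat = runif(40, 47.5, 50), lon = runif(40, 9.5, 13),
                    elevation_m = runif(40, 200, 1200),
                    species = "Betula", year = 2010L, onset_doy = 100L)
  mu <- truth[1] + truth[2] * obs$elevation_m + truth[3] * obs$lon +
    truth[4] * obs$lat
  obs$onset_doy <- mu
  m <- fit_circle_model(obs, big_circle())
  expect_equal(unname(c(m$a0, m$a1, m$a2, m$a3)), truth, tolerance = 1e-8)
  expect_lt(m$rmse, 1e-8)
  expect_equal(m$n_obs, 40L)

  expect_null(fit_circle_model(obs[1:3, ], big_circle(), min_n = 10))
  # rank-deficient design (all sites identical) is a skip, not an error
  flat <- obs[rep(1L, 12L), ]
  expect_null(fit_circle_model(flat, big_circle()))
  # observations outside the circle never influence the fit
  far <- obs[1, ]; far$lat <- 30; far$onset_doy <- 999
  m2 <- fit_circle_model(rbind(obs, far), big_circle())
  expect_equal(c(m2$a0, m2$a1, m2$a2, m2$a3), c(m$a0, m$a1, m$a2, m$a3))
})

test_that("circle fits agree with a normal-equations oracle", {
  for (seed in c(2, 9, 31)) {
    set.seed(seed)
    obs <- data.frame(site_id = sprintf("S%02d", 1:30),
                      lat = runif(30, 47.5, 50), lon = runif(30, 9.5, 13),
                      elevation_m = runif(30, 200, 1200),
                      species = "Betula", year = 2010L,
                      onset_doy = runif(30, 80, 140))
    m <- fit_circle_model(obs, big_circle())
    beta <- normal_equations_ols(
      cbind(1, obs$elevation_m, obs$lon, obs$lat), obs$onset_doy)
    expect_equal(unname(c(m$a0, m$a1, m$a2, m$a3)), unname(beta),
                 tolerance = 1e-8)
  }
})

make_model <- function(lat, lon, coefs, r = 3) {
  structure(list(circle = big_circle(lat, lon, r), a0 = coefs[1],
                 a1 = coefs[2], a2 = coefs[3], a3 = coefs[4],
                 n_obs = 99L, rmse = 0), class = "circle_model")
}

test_that("coefficient interpolation follows inverse distance weighting", {
  coefs <- c(60, 0.03, -2, 4)
  models <- list(make_model(47, 10, coefs), make_model(49, 12, coefs),
                 make_model(48, 11, coefs))
  expect_equal(unname(interpolate_coefficients(models, 48.3, 10.7)),
               coefs)

  # distance-zero rule: a target on a centre takes that circle verbatim
  models2 <- list(make_model(47, 10, c(50, 0, 0, 0)),
                  make_model(49, 12, c(70, 0, 0, 0)),
                  make_model(48, 11, c(90, 1, 1, 1)))
  expect_equal(unname(interpolate_coefficients(models2, 48, 11)),
               c(90, 1, 1, 1))

  # hand-computed three-circle case (weights 1/d^2, normalised)
  a0s <- c(50, 70, 90)
  d <- geosphere::distHaversine(
    cbind(c(10, 12, 11), c(47, 49, 48)), c(10.7, 48.3), r = 6378.137)
  w <- (1 / d^2) / sum(1 / d^2)
  got <- interpolate_coefficients(models2, 48.3, 10.7)
  expect_equal(unname(got[1L]), sum(w * a0s), tolerance = 1e-12)

  # convex-hull containment per coefficient
  for (seed in 1:20) {
    set.seed(seed)
    ms <- lapply(1:5, function(i)
      make_model(runif(1, 46, 50), runif(1, 9, 13), rnorm(4)))
    a <- interpolate_coefficients(ms, runif(1, 46, 50), runif(1, 9, 13))
    lims <- sapply(ms, function(m) c(m$a0, m$a1, m$a2, m$a3))
    expect_true(all(a >= apply(lims, 1, min) - 1e-12))
    expect_true(all(a <= apply(lims, 1, max) + 1e-12))
  }

  expect_error(interpolate_coefficients(models[1], 48, 11),
               "coverage error")
})

test_that("grid prediction evaluates the onset regression per pixel", {
  m <- make_model(48, 11, c(60, 0.03, -2, 4), r = 5)
  grid <- data.frame(lat = 48, lon = 11, elevation_m = 500)
  surf <- predict_doy_grid(list(m), grid, k_min = 1)
  expect_equal(surf$pixels$sos_f, 60 + 15 - 22 + 192)   # 245

  # elevation-only gradient: prediction strictly increases with elevation
  m <- make_model(48, 11, c(60, 0.05, 0, 0), r = 5)
  grid <- data.frame(lat = rep(48, 5), lon = rep(11, 5),
                     elevation_m = seq(200, 1000, by = 200))
  surf <- predict_doy_grid(list(m), grid, k_min = 1)
  expect_true(all(diff(surf$pixels$sos_f) > 0))

  # a pixel outside every circle stays unpredicted and is counted
  grid <- data.frame(lat = c(48, 20), lon = c(11, 11),
                     elevation_m = c(500, 500))
  surf <- predict_doy_grid(list(m), grid, k_min = 1)
  expect_true(is.na(surf$pixels$sos_f[2L]))
  expect_equal(surf$n_uncovered, 1L)
})

test_that("noise-free networks are reproduced pixel-exact end to end", {
  truth <- c(60, 0.03, -2, 4)
  net <- simulate_pheno_network(coef = truth, n_sites = 120, noise_sd = 0,
                                seed = 6)
  circles <- make_circles(net$obs, n_circles = 9, radius_deg = 2.5)
  models <- lapply(seq_len(nrow(circles)), function(i)
    fit_circle_model(net$obs, circles[i, ]))
  expect_gt(sum(!vapply(models, is.null, logical(1))), 2L)
  grid <- expand.grid(lat = seq(47.5, 50.3, by = 0.4),
                      lon = seq(9.2, 13.6, by = 0.4))
  grid$elevation_m <- 300 + 10 * (grid$lat - 47) * (grid$lon - 9)
  surf <- predict_doy_grid(models, grid)
  want <- truth[1] + truth[2] * grid$elevation_m + truth[3] * grid$lon +
    truth[4] * grid$lat
  ok <- !is.na(surf$pixels$sos_f)
  expect_gt(mean(ok), 0.9)
  # observations are rounded to whole days, so recovery is day-accurate
  expect_lt(max(abs(surf$pixels$sos_f[ok] - want[ok])), 0.5)
})

test_that("station extraction uses half-open pixel cells", {
  m <- make_model(48, 11, c(100, 0, 0, 0), r = 5)
  grid <- expand.grid(lat = seq(47.6, 48.4, by = 0.2),
                      lon = seq(10.6, 11.4, by = 0.2))
  grid$elevation_m <- 400
  surf <- predict_doy_grid(list(m), grid, k_min = 1)
  expect_equal(extract_site_sosf(surf, 48.0, 11.0), 100)
  # boundary point: lower-left inclusive
  expect_equal(extract_site_sosf(surf, 47.9, 10.9), 100)
  expect_error(extract_site_sosf(surf, 30, 11), "outside the covered grid")

  # extraction is consistent with direct evaluation at the pixel
  m2 <- make_model(48, 11, c(60, 0.03, -2, 4), r = 5)
  surf2 <- predict_doy_grid(list(m2), grid, k_min = 1)
  a <- interpolate_coefficients(list(m2), 48.0, 11.0, k_min = 1)
  expect_equal(extract_site_sosf(surf2, 48.0, 11.0, rounded = FALSE),
               a[1] + a[2] * 400 + a[3] * 11.0 + a[4] * 48.0,
               ignore_attr = TRUE)
})

fake_surface <- function(grid, sos_f, year)
  structure(list(species = "Betula", year = year,
                 pixels = cbind(grid, sos_f = sos_f,
                                sos_f_day = as.integer(round(sos_f))),
                 n_uncovered = 0L),
            class = "flowering_surface")

test_that("pixel trend distributions flag deviating station trends", {
  grid <- expand.grid(lat = seq(47.5, 50, by = 0.25),
                      lon = seq(9.5, 13, by = 0.25))
  grid$elevation_m <- 500
  base <- 100 + 2 * (grid$lat - 47)
  years <- 2001:2010

  shifted <- lapply(seq_along(years), function(i)
    fake_surface(grid, base - 0.5 * (i - 1), years[i]))
  dist <- pixel_trend_distribution(shifted, years)
  expect_equal(unname(dist$quantiles[["50%"]]), -0.5, tolerance = 1e-10)
  expect_true(all(abs(dist$slopes + 0.5) < 1e-10))
  expect_false(dist$contains(-2.0))
  expect_true(dist$contains(-0.5))

  constant <- lapply(years, function(y) fake_surface(grid, base, y))
  dist0 <- pixel_trend_distribution(constant, years)
  expect_true(all(abs(dist0$slopes) < 1e-12))

  # quantiles agree with a sorting-based oracle on noisy slopes
  set.seed(14)
  noisy <- lapply(seq_along(years), function(i)
    fake_surface(grid, base - 0.3 * (i - 1) +
                   rnorm(nrow(grid), sd = 2), years[i]))
  dn <- pixel_trend_distribution(noisy, years)
  for (p in c(0.025, 0.25, 0.5, 0.75, 0.975))
    expect_equal(unname(dn$quantiles[[sprintf("%g%%", 100 * p)]]),
                 sort_quantile_oracle(dn$slopes, p), tolerance = 1e-10)

  expect_error(pixel_trend_distribution(shifted[1:2], years[1:2]),
               "at least 3")
  bad <- shifted; bad[[2L]]$pixels$lat <- bad[[2L]]$pixels$lat + 1
  expect_error(pixel_trend_distribution(bad, years), "inconsistent grids")
})
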