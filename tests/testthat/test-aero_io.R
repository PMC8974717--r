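# Readers/writers for pollen tables, phenology tables, HYSPLIT endpoint
# files and the packaged difference table.

test_that("pollen table round-trips through CSV and validates its input", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,date,taxon,concentration",
               "E,2010-02-09,Corylus,0",
               "E,2010-02-10,Corylus,5",
               "E,2010-02-11,Corylus,3"), csv)
  series <- read_pollen_table(csv)
  expect_length(series, 1L)
  s <- series[[1L]]
  expect_equal(s$doy, c(40L, 41L, 42L))
  expect_equal(s$conc, c(0, 5, 3))
  expect_equal(s$first_operation_doy, 40L)

  # write-then-read identity on a generated series with missing days
  sim <- simulate_pollen_year(noise_sd = 3, seed = 11,
                              missing_spells = list(c(120L, 4L)))
  out <- withr::local_tempfile(fileext = ".csv")
  write_pollen_table(sim$series, out)
  back <- read_pollen_table(out)[[1L]]
  expect_equal(back$doy, sim$series$doy)
  expect_equal(back$conc, sim$series$conc)
  expect_equal(back$taxon, sim$series$taxon)
})

test_that("pollen reader rejects duplicates, bad dates and negatives", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,date,taxon,concentration",
               "E,2010-02-10,Corylus,5",
               "E,2010-02-10,Corylus,7"), csv)
  expect_error(read_pollen_table(csv), "E/2010-02-10/Corylus")

  writeLines(c("station_id,date,taxon,concentration",
               "E,10.02.2010,Corylus,5"), csv)
  expect_error(read_pollen_table(csv), "malformed date.*row")

  writeLines(c("station_id,date,taxon,concentration",
               "E,2010-02-10,Corylus,-2"), csv)
  expect_error(read_pollen_table(csv), "negative concentration")
})

test_that("pollen reader honours a custom column dialect", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trap,day,pollen_type,grains",
               "E,2010-02-10,Corylus,5"), csv)
  d <- pollen_dialect(station_id = "trap", date = "day",
                      taxon = "pollen_type", concentration = "grains")
  s <- read_pollen_table(csv, dialect = d)
  expect_equal(s[[1L]]$conc, 5)
  expect_error(read_pollen_table(csv), "required columns absent")
})

test_that("phenology table round-trips and enforces ranges", {
  obs <- data.frame(site_id = c("A", "B"), lat = c(48.1, 49.5),
                    lon = c(11.6, 11.0), elevation_m = c(520, 300),
                    species = "Betula", year = 2010L,
                    onset_doy = c(110L, 104L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pheno_table(as_pheno_observations(obs), path)
  back <- read_pheno_table(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$onset_doy, obs$onset_doy)
  expect_equal(back$lat, obs$lat)

  bad <- obs; bad$lat[1L] <- 120
  expect_error(as_pheno_observations(bad), "latitude out of range")
  bad <- obs; bad$elevation_m[2L] <- NA
  expect_error(as_pheno_observations(bad), "elevation")
})

test_that("tdump files written by the simulator parse back", {
  path <- withr::local_tempfile(fileext = ".tdump")
  trajs <- simulate_trajectories(48.1, 11.6, origin_bearing_deg = 225,
                                 distance_km = 600, jitter_km = 15,
                                 seed = 4, tdump_path = path)
  back <- parse_tdump(path)
  expect_length(back, 8L)
  for (k in seq_along(back)) {
    expect_equal(nrow(back[[k]]$points), 25L)
    expect_equal(back[[k]]$points$lat, trajs[[k]]$points$lat,
                 tolerance = 1e-4)
    expect_equal(back[[k]]$points$lon, trajs[[k]]$points$lon,
                 tolerance = 1e-4)
    expect_equal(back[[k]]$points$age_hours, trajs[[k]]$points$age_hours)
  }
})

test_that("tdump parser handles degenerate and out-of-window input", {
  # hand-built two-trajectory, three-endpoint file
  path <- withr::local_tempfile()
  writeLines(c(
    "     1     1",
    "    SYNT    10     4     1     0     0",
    "     2 BACKWARD OMEGA",
    "    10     4     1     0    48.000    11.000     500.0",
    "    10     4     1     3    48.000    11.000     500.0",
    "     1 PRESSURE",
    "  1 1 10  4  1  0  0  0    0.0  48.0000  11.0000   500.0   900.0",
    "  1 1 10  3 31 21  0  0   -3.0  47.9000  10.9000   500.0   900.0",
    "  1 1 10  3 31 18  0  0   -6.0  47.8000  10.8000   500.0   900.0",
    "  2 1 10  4  1  3  0  0    0.0  48.0000  11.0000   500.0   900.0",
    "  2 1 10  4  1  0  0  0   -3.0  47.9500  10.9500   500.0   900.0",
    "  2 1 10  3 31 21  0  0   -6.0  47.9000  10.9000   500.0   900.0"),
    path)
  trajs <- parse_tdump(path)
  expect_length(trajs, 2L)
  expect_equal(vapply(trajs, function(t) nrow(t$points), integer(1)),
               c(3L, 3L))
  expect_equal(trajs[[1L]]$points$age_hours, c(0, -3, -6))

  # endpoint beyond the 72 h window: retained but flagged
  writeLines(c(
    "     1     1",
    "    SYNT    10     4     1     0     0",
    "     1 BACKWARD OMEGA",
    "    10     4     1     0    48.000    11.000     500.0",
    "     1 PRESSURE",
    "  1 1 10  4  1  0  0  0    0.0  48.0000  11.0000   500.0   900.0",
    "  1 1 10  3 29  0  0  0  -75.0  45.0000   8.0000   500.0   900.0"),
    path)
  expect_warning(trajs <- parse_tdump(path), "beyond 72 h")
  expect_equal(nrow(trajs[[1L]]$points), 2L)
  expect_true("BEYOND_72H" %in% trajs[[1L]]$flags)

  # empty endpoint section
  writeLines(c(
    "     1     1",
    "    SYNT    10     4     1     0     0",
    "     1 BACKWARD OMEGA",
    "    10     4     1     0    48.000    11.000     500.0",
    "     1 PRESSURE"), path)
  expect_warning(trajs <- parse_tdump(path), "no endpoint records")
  expect_length(trajs, 0L)

  # truncated endpoint record names its line
  writeLines(c(
    "     1     1",
    "    SYNT    10     4     1     0     0",
    "     1 BACKWARD OMEGA",
    "    10     4     1     0    48.000    11.000     500.0",
    "     1 PRESSURE",
    "  1 1 10  4  1  0  0"), path)
  expect_error(parse_tdump(path), "line 6: truncated")

  # unknown trajectory index
  writeLines(c(
    "     1     1",
    "    SYNT    10     4     1     0     0",
    "     1 BACKWARD OMEGA",
    "    10     4     1     0    48.000    11.000     500.0",
    "     1 PRESSURE",
    "  3 1 10  4  1  0  0  0    0.0  48.0000  11.0000   500.0   900.0"),
    path)
  expect_error(parse_tdump(path), "unknown trajectory index")
})

test_that("the packaged difference table matches its source", {
  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 31L * 21L)
  # study window: Munich/Oberjoch 2005-2015 plus Erlangen 2005-2012
  w <- table2_study_window(t2)
  expect_equal(nrow(w), 209L)
  expect_equal(
    t2$diff_days[t2$station == "Oberjoch" & t2$taxon == "Corylus" &
                   t2$year == 2013L], -88L)
  erl14 <- t2[t2$station == "Erlangen" & t2$year == 2014L, ]
  expect_true(all(is.na(erl14$diff_days)))
  expect_true(all(erl14$missing_reason == "n.a."))
  # the two missing reasons stay distinct
  expect_setequal(unique(t2$missing_reason), c("", "n.a.", "d."))
  expect_equal(sum(t2$missing_reason == "d."), 13L)
})
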