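Package: pollenclim
Title: Pollen Season Definition and Pre-Season Transport Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building a pre-season pollen-transport climatology from
    daily airborne pollen concentrations and ground phenological observations.
    Defines pollen-season parameters (start, peak, end, annual integral) by the
    percentage method with linear imputation of missing days; interpolates
    flowering onset dates to a spatial surface via regional regressions on
    elevation, longitude and latitude combined with inverse distance weighting;
    classifies station-by-taxon-by-year cases as local, pre-season transport or
    faulty from the mismatch between pollen and flowering start dates; and
    confirms hypothesized transport events with green-wave flowering dates
    extrapolated along HYSPLIT back-trajectory footprints. Includes a
    synthetic-data generator with known ground truth and a packaged
    transcription of a published station-by-taxon-by-year difference table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
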