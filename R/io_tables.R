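# Readers and writers for the pipeline's tabular inputs. CSV column names
# are adapted through a small "dialect" mapping so arbitrary provider
# headers can be used without renaming files.

#' Column dialect for pollen concentration tables
#'
#' Maps the canonical column roles to the header names found in a file.
#'
#' @param station_id,date,taxon,concentration header names in the CSV.
#' @return named character vector used by [read_pollen_table()].
#' @export
pollen_dialect <- function(station_id = "station_id", date = "date",
                           taxon = "taxon", concentration = "concentration") {
  c(station_id = station_id, date = date, taxon = taxon,
    concentration = concentration)
}

#' Column dialect for phenological observation tables
#'
#' @param site_id,lat,lon,elevation_m,species,year,onset_doy header names.
#' @return named character vector used by [read_pheno_table()].
#' @export
pheno_dialect <- function(site_id = "site_id", lat = "lat", lon = "lon",
                          elevation_m = "elevation_m", species = "species",
                          year = "year", onset_doy = "onset_doy") {
  c(site_id = site_id, lat = lat, lon = lon, elevation_m = elevation_m,
    species = species, year = year, onset_doy = onset_doy)
}

remap_columns <- function(df, dialect, path) {
  miss <- setdiff(unname(dialect), names(df))
  if (length(miss))
    stop(sprintf("%s: required columns absent: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  out <- df[, unname(dialect), drop = FALSE]
  names(out) <- names(dialect)
  out
}

#' Read a daily pollen concentration table
#'
#' Reads a CSV of daily Hirst-trap style concentrations (one row per
#' station, ISO date and taxon) and splits it into one
#' [daily_pollen_series()] per station-by-taxon-by-year. Dates are converted
#' to day-of-year; the trap start of a station-year (smallest recorded day
#' across all its taxa) is attached to each series.
#'
#' @param path CSV file path.
#' @param dialect column mapping from [pollen_dialect()].
#' @return a list of `daily_pollen_series`, named `station/taxon/year`.
#' @export
read_pollen_table <- function(path, dialect = pollen_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- remap_columns(raw, dialect, path)
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date))
    stop(sprintf("%s: malformed date in row(s) %s", path,
                 paste(utils::head(which(is.na(date)), 5L), collapse = ", ")),
         call. = FALSE)
  conc <- suppressWarnings(as.numeric(df$concentration))
  if (any(conc < 0, na.rm = TRUE))
    stop(sprintf("%s: negative concentration in row(s) %s", path,
                 paste(utils::head(which(conc < 0), 5L), collapse = ", ")),
         call. = FALSE)
  key <- paste(df$station_id, df$date, df$taxon, sep = "/")
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicated station/date/taxon row: %s", path,
                 key[which(duplicated(key))[1L]]), call. = FALSE)
  year <- as.integer(format(date, "%Y"))
  doy <- date_to_doy(date)
  op_start <- tapply(doy, paste(df$station_id, year, sep = "/"), min)
  split_key <- paste(df$station_id, df$taxon, year, sep = "/")
  out <- lapply(split(seq_len(nrow(df)), split_key), function(i) {
    ord <- i[order(doy[i])]
    daily_pollen_series(
      station_id = df$station_id[ord[1L]], taxon = df$taxon[ord[1L]],
      year = year[ord[1L]], doy = doy[ord], conc = conc[ord],
      first_operation_doy = op_start[[paste(df$station_id[ord[1L]],
                                            year[ord[1L]], sep = "/")]])
  })
  out[order(names(out))]
}

#' Write daily pollen series back to CSV
#'
#' Inverse of [read_pollen_table()]: emits ISO dates reconstructed from the
#' series year and day-of-year. Missing days are written with an empty
#' concentration field.
#'
#' @param series a `daily_pollen_series` or list of them.
#' @param path output CSV path.
#' @param dialect column mapping; controls the written header names.
#' @return `path`, invisibly.
#' @export
write_pollen_table <- function(series, path, dialect = pollen_dialect()) {
  if (inherits(series, "daily_pollen_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(station_id = s$station_id,
               date = format(doy_to_date(s$doy, s$year), "%Y-%m-%d"),
               taxon = s$taxon, concentration = s$conc,
               stringsAsFactors = FALSE)
  }))
  names(rows) <- unname(dialect[c("station_id", "date", "taxon",
                                  "concentration")])
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a phenological observation table
#'
#' @param path CSV file path.
#' @param dialect column mapping from [pheno_dialect()].
#' @return a validated `pheno_observations` data frame (one row per
#'   site-by-species-by-year).
#' @export
read_pheno_table <- function(path, dialect = pheno_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- remap_columns(raw, dialect, path)
  df$onset_doy <- as.integer(df$onset_doy)
  df$year <- as.integer(df$year)
  as_pheno_observations(df)
}

#' Write a phenological observation table
#'
#' @param obs a `pheno_observations` data frame.
#' @param path output CSV path.
#' @param dialect column mapping; controls the written header names.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(obs, path, dialect = pheno_dialect()) {
  out <- as.data.frame(obs)[, names(dialect)]
  names(out) <- unname(dialect)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
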