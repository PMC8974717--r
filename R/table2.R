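# Packaged transcription of the published station-by-taxon-by-year table of
# differences between the start of the pollen season and the start of the
# interpolated flowering season (SOS_P - SOS_F, days) at Erlangen, Munich
# and Oberjoch, 1987-2017.

TABLE2_MD5 <- "6a30a3da0aa255f69f81a28875c06fbe"

#' Load the packaged SOS_P - SOS_F difference table
#'
#' Returns the transcribed station-by-taxon-by-year differences (days)
#' between pollen-season start and interpolated flowering start for the
#' stations Erlangen, Munich and Oberjoch (1987-2017, seven taxa). Missing
#' cells carry `NA` with the transcription's reason preserved: `"n.a."`
#' (not measured) or `"d."` (discarded by the original quality screening).
#'
#' @param check verify the md5 checksum of the packaged file (default TRUE).
#' @return data frame with columns `station`, `taxon`, `year`, `diff_days`
#'   (integer, `NA` when missing) and `missing_reason` (`""`, `"n.a."` or
#'   `"d."`).
#' @examples
#' t2 <- load_table2_fixture()
#' subset(t2, station == "Oberjoch" & taxon == "Corylus" & year == 2013)
#' @export
load_table2_fixture <- function(check = TRUE) {
  path <- system.file("extdata", "table2_sos_differences.csv",
                      package = "pollenclim", mustWork = TRUE)
  if (check) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, TABLE2_MD5))
      stop("packaged difference table failed its integrity check (md5 ",
           got, ")", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(station = "character",
                                       taxon = "character", year = "integer",
                                       diff_days = "integer",
                                       missing_reason = "character"))
  df$missing_reason[is.na(df$missing_reason)] <- ""
  stopifnot(all(is.na(df$diff_days) == (df$missing_reason != "")),
            all(abs(df$diff_days) <= 100, na.rm = TRUE))
  df
}

#' Restrict the difference table to the trajectory-study window
#'
#' The transport climatology was evaluated on Munich and Oberjoch 2005-2015
#' and Erlangen 2005-2012; this helper applies that window.
#'
#' @param table2 output of [load_table2_fixture()].
#' @param drop_missing drop cells with no measured difference (default TRUE).
#' @return the filtered data frame (209 rows with defaults).
#' @export
table2_study_window <- function(table2, drop_missing = TRUE) {
  keep <- (table2$station %in% c("Munich", "Oberjoch") &
             table2$year >= 2005 & table2$year <= 2015) |
    (table2$station == "Erlangen" & table2$year >= 2005 & table2$year <= 2012)
  out <- table2[keep, , drop = FALSE]
  if (drop_missing) out <- out[!is.na(out$diff_days), , drop = FALSE]
  rownames(out) <- NULL
  out
}
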