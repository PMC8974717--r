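# Rule-based classification of each station/taxon/year case from the
# difference between pollen-season start and local flowering start, the
# cross-station long-range rule, and the climatology summaries.

SOURCE_CLASSES <- c("PRE_SEASON_TRANSPORT", "LOCAL", "NO_LOCAL_OR_FAULTY")
TRANSPORT_TYPES <- c("LONG_RANGE_OUTSIDE_REGION", "LONG_RANGE",
                     "UNDEFINED_RANGE", "NOT_APPLICABLE")

#' Classify a case from the pollen-minus-flowering start difference
#'
#' Applies the three-interval rule to `diff = SOS_P - SOS_F` (days):
#' `diff <= -threshold` is pre-season transport, `-threshold < diff <
#' threshold` local sources, `diff >= threshold` no local sources or faulty
#' recording (closed outer intervals, so exactly -10 is transport and
#' exactly +10 is faulty at the default threshold). At an alpine station
#' with no local sources of the taxon, a nominally "local" difference is
#' still attributed to transport.
#'
#' @param diff SOS_P - SOS_F in days (vectorised).
#' @param station_kind `"lowland"` or `"alpine"` (scalar or vector).
#' @param threshold local-window half-width in days (default 10).
#' @return character vector over `PRE_SEASON_TRANSPORT`, `LOCAL`,
#'   `NO_LOCAL_OR_FAULTY`.
#' @export
classify_case <- function(diff, station_kind = "lowland", threshold = 10) {
  stopifnot(all(is.finite(diff)), threshold > 0,
            all(station_kind %in% c("lowland", "alpine")))
  cls <- ifelse(diff <= -threshold, "PRE_SEASON_TRANSPORT",
                ifelse(diff >= threshold, "NO_LOCAL_OR_FAULTY", "LOCAL"))
  alpine <- rep_len(station_kind == "alpine", length(diff))
  cls[alpine & cls == "LOCAL"] <- "PRE_SEASON_TRANSPORT"
  cls
}

#' Transport-type label for a pre-season transport case
#'
#' An alpine case whose pollen start precedes the lowland reference
#' flowering by at least `threshold` days is attributed to long-range
#' transport from outside the region. Otherwise, a pollen start within
#' `same_day_window` days of another station's start points to long-range
#' transport; remaining cases stay of undefined range.
#'
#' @param sos_p season start (day-of-year) of the case.
#' @param station_kind `"lowland"` or `"alpine"`.
#' @param other_station_sos_p season starts of the other stations for the
#'   same taxon and year (may be empty).
#' @param alpine_ref_sos_f lowland reference flowering start used for the
#'   alpine rule (e.g. mean of the lowland stations' SOS_F).
#' @param threshold days, default 10; `same_day_window` days, default 3
#'   (strict inequality: a 3-day difference does not qualify).
#' @return one of `LONG_RANGE_OUTSIDE_REGION`, `LONG_RANGE`,
#'   `UNDEFINED_RANGE`.
#' @export
flag_longrange <- function(sos_p, station_kind = "lowland",
                           other_station_sos_p = numeric(0),
                           alpine_ref_sos_f = NA_real_, threshold = 10,
                           same_day_window = 3) {
  if (station_kind == "alpine" && is.finite(alpine_ref_sos_f) &&
      sos_p <= alpine_ref_sos_f - threshold)
    return("LONG_RANGE_OUTSIDE_REGION")
  other <- other_station_sos_p[is.finite(other_station_sos_p)]
  if (!length(other)) {
    if (station_kind != "alpine" || !is.finite(alpine_ref_sos_f))
      warning("no other-station season starts available; range undefined",
              call. = FALSE)
    return("UNDEFINED_RANGE")
  }
  if (min(abs(sos_p - other)) < same_day_window) "LONG_RANGE"
  else "UNDEFINED_RANGE"
}

#' Build case records from a difference table
#'
#' Turns rows of station/taxon/year differences (such as the packaged
#' table, see [load_table2_fixture()]) into classified case records.
#' Reliability follows the numeric screening: a taxon listed in
#' `unreliable_taxa` (interpolated flowering known to be weak) or a
#' difference at or above `+threshold` (too-late pollen recording) marks a
#' case unreliable, with the reason kept — never silently dropped.
#'
#' @param diffs data frame with columns `station`, `taxon`, `year`,
#'   `diff_days`.
#' @param alpine_stations station names treated as alpine (default
#'   `"Oberjoch"`).
#' @param local_source_taxa taxa with genuine local sources even at alpine
#'   stations (default Pinus and Poaceae): for these the alpine remap is
#'   not applied.
#' @param unreliable_taxa taxa flagged unreliable throughout (default
#'   `"Artemisia"`).
#' @param threshold classification threshold in days (default 10).
#' @return data frame of class records: `station`, `taxon`, `year`, `diff`,
#'   `station_kind`, `source_class`, `reliable`, `reliability_reason`.
#' @export
build_case_records <- function(diffs, alpine_stations = "Oberjoch",
                               local_source_taxa = c("Pinus", "Poaceae"),
                               unreliable_taxa = "Artemisia",
                               threshold = 10) {
  d <- diffs[is.finite(diffs$diff_days), , drop = FALSE]
  kind <- ifelse(d$station %in% alpine_stations &
                   !(d$taxon %in% local_source_taxa), "alpine", "lowland")
  cls <- classify_case(d$diff_days, kind, threshold = threshold)
  reason <- character(nrow(d))
  reason[d$taxon %in% unreliable_taxa] <- "unreliable_taxon"
  late <- d$diff_days >= threshold & reason == ""
  reason[late] <- "late_pollen_recording"
  data.frame(station = d$station, taxon = d$taxon, year = d$year,
             diff = d$diff_days, station_kind = kind, source_class = cls,
             reliable = reason == "", reliability_reason = reason,
             stringsAsFactors = FALSE)
}

#' Summarise the transport climatology of a set of cases
#'
#' Medians (mean of the two central order statistics for even n), extrema
#' and source-class breakdowns, overall and per requested grouping.
#'
#' @param cases data frame from [build_case_records()] (needs `diff` and
#'   `source_class`).
#' @param by optional character vector of grouping columns (e.g.
#'   `c("station", "taxon")`) for per-group medians.
#' @param exclude_unreliable drop cases with `reliable == FALSE` before
#'   summarising (default FALSE).
#' @return list of class `climatology_summary`: `n`, `median`, `min`,
#'   `max`, `class_counts`, `class_pct` (percent of n, over the three
#'   source classes), and `groups` (data frame of per-group n/median/min/
#'   max when `by` is given).
#' @export
summarize_climatology <- function(cases, by = NULL,
                                  exclude_unreliable = FALSE) {
  if (exclude_unreliable && "reliable" %in% names(cases))
    cases <- cases[cases$reliable, , drop = FALSE]
  if (!nrow(cases)) stop("no cases to summarise", call. = FALSE)
  counts <- table(factor(cases$source_class, levels = SOURCE_CLASSES))
  out <- list(n = nrow(cases), median = stats::median(cases$diff),
              min = min(cases$diff), max = max(cases$diff),
              class_counts = counts,
              class_pct = 100 * as.numeric(counts) / nrow(cases))
  names(out$class_pct) <- SOURCE_CLASSES
  if (!is.null(by)) {
    key <- interaction(cases[by], drop = TRUE, sep = "/")
    grp <- do.call(rbind, lapply(split(cases, key), function(g) {
      cbind(g[1L, by, drop = FALSE],
            data.frame(n = nrow(g), median = stats::median(g$diff),
                       min = min(g$diff), max = max(g$diff)))
    }))
    rownames(grp) <- NULL
    out$groups <- grp
  }
  class(out) <- "climatology_summary"
  out
}

#' @export
print.climatology_summary <- function(x, ...) {
  cat(sprintf("<climatology_summary> %d cases: median %+g days (%+g..%+g)\n",
              x$n, x$median, x$min, x$max))
  pct <- sprintf("%s %.1f%%", names(x$class_pct), x$class_pct)
  cat(" ", paste(pct, collapse = ", "), "\n")
  if (!is.null(x$groups)) cat(sprintf("  %d group rows\n", nrow(x$groups)))
  invisible(x)
}

#' Compare season-start concentrations between two source classes
#'
#' Two-sided Welch t-test of the daily concentrations on season-start days,
#' e.g. transport years versus local-source years.
#'
#' @param group_a,group_b numeric concentration samples (n >= 2 each).
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_sos_concentrations <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop(paste("both groups are constant; the t-test is undefined",
               "(consider an exact tie-aware test)"), call. = FALSE)
  stats::t.test(group_a, group_b, var.equal = FALSE)
}
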