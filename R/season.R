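# Pollen-season definition: linear ("lineal") imputation of missing days,
# the percentage method for season start/peak/end, clinical intensity
# classes, reliability screening of season starts, and linear trends.

#' Linearly impute interior missing days of a pollen series
#'
#' Fills each interior run of missing days by linear interpolation between
#' the nearest present neighbours ("lineal" imputation). Present values are
#' never altered; leading and trailing missing days cannot be bracketed and
#' stay missing (flagged in the returned series' `imputation_flags`).
#'
#' @param series a [daily_pollen_series()].
#' @return the series with interior `NA`s replaced; attribute fields
#'   `imputed_doy` (days filled) and `imputation_flags`.
#' @examples
#' s <- daily_pollen_series("E", "Betula", 2010, 10:12, c(4, NA, 8))
#' impute_lineal(s)$conc   # 4 6 8
#' @export
impute_lineal <- function(series) {
  stopifnot(inherits(series, "daily_pollen_series"))
  present <- !is.na(series$conc)
  if (sum(present) < 2L) {
    if (!any(present)) stop("all values missing; nothing to interpolate",
                            call. = FALSE)
    stop("at least two present values required for interpolation",
         call. = FALSE)
  }
  filled <- stats::approx(series$doy[present], series$conc[present],
                          xout = series$doy, method = "linear",
                          rule = 1)$y
  out <- series
  was_na <- is.na(series$conc)
  out$conc <- ifelse(was_na, filled, series$conc)
  out$imputed_doy <- series$doy[was_na & !is.na(filled)]
  out$imputation_flags <- character(0)
  if (any(was_na & is.na(filled)))
    out$imputation_flags <- "EDGE_MISSING"
  out$premask_missing <- series$doy[was_na]   # pre-imputation mask, kept for
  out                                          # the >20% in-season rule
}

#' Define pollen-season parameters by the percentage method
#'
#' Trims the earliest and latest `alpha`% of the annual cumulative pollen
#' amount: the season start (SOS_P) is the first day at which the cumulative
#' sum reaches `alpha`% of the annual total, the end (EOS_P) the first day
#' at which it reaches `100 - alpha`%. The peak (PEAK_P) is the day of the
#' maximum daily concentration (earliest day on ties) and SUM_P the annual
#' pollen integral (sum of all daily concentrations).
#'
#' @param series an imputed [daily_pollen_series()]; remaining `NA` days are
#'   treated as zero contribution but counted in the missing fraction.
#' @param alpha trimmed percentage at each tail (default 2.5). `alpha = 0`
#'   gives the first and last day with nonzero concentration.
#' @return object of class `season_params`: list with `station_id`, `taxon`,
#'   `year`, `sos_p`, `peak_p`, `eos_p`, `sum_p`,
#'   `missing_fraction_in_season` (pre-imputation missing share within
#'   [SOS_P, EOS_P], when the series carries its pre-imputation mask) and
#'   `flags`.
#' @export
define_season_percentage <- function(series, alpha = 2.5) {
  stopifnot(inherits(series, "daily_pollen_series"))
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha < 0 || alpha >= 50) stop("`alpha` must be in [0, 50)",
                                     call. = FALSE)
  conc <- ifelse(is.na(series$conc), 0, series$conc)
  total <- sum(conc)
  if (total <= 0)
    stop("zero annual pollen total: season undefined", call. = FALSE)
  cs <- cumsum(conc)
  sos_i <- if (alpha == 0) which(conc > 0)[1L] else
    which(cs >= alpha / 100 * total)[1L]
  eos_i <- if (alpha == 0) max(which(conc > 0)) else
    which(cs >= (100 - alpha) / 100 * total)[1L]
  peak_i <- which.max(conc)             # earliest day on ties
  sos <- series$doy[sos_i]; eos <- series$doy[eos_i]
  miss_frac <- NA_real_
  if (!is.null(series$premask_missing)) {
    in_season <- series$doy >= sos & series$doy <= eos
    miss_frac <- sum(series$premask_missing >= sos &
                       series$premask_missing <= eos) / sum(in_season)
  }
  structure(
    list(station_id = series$station_id, taxon = series$taxon,
         year = series$year, sos_p = sos, peak_p = series$doy[peak_i],
         eos_p = eos, sum_p = total,
         missing_fraction_in_season = miss_frac, flags = character(0)),
    class = "season_params")
}

#' @export
print.season_params <- function(x, ...) {
  cat(sprintf(
    "<season_params> %s / %s / %d: SOS %d, PEAK %d, EOS %d, SUM %.1f\n",
    x$station_id, x$taxon, x$year, x$sos_p, x$peak_p, x$eos_p, x$sum_p))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# --- pluggable season-method registry ------------------------------------

season_method_registry <- new.env(parent = emptyenv())

#' Register or look up alternative season-definition methods
#'
#' The percentage method ships built in; other conventions (logistic,
#' moving, clinical, grains, ...) can be plugged in by name. A method is a
#' `function(series, ...)` returning a `season_params`.
#'
#' @param name method name.
#' @param fun the implementing function (omit to look the name up).
#' @return `register_season_method` returns `fun` invisibly;
#'   `season_methods` returns the registered names.
#' @export
register_season_method <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = season_method_registry)
  invisible(fun)
}

#' @rdname register_season_method
#' @export
season_methods <- function() sort(ls(season_method_registry))

#' Define a pollen season by a named method
#'
#' @param series an imputed [daily_pollen_series()].
#' @param method registered method name (default `"percentage"`).
#' @param ... passed to the method function.
#' @return a `season_params` object.
#' @export
define_season <- function(series, method = "percentage", ...) {
  if (!exists(method, envir = season_method_registry))
    stop(sprintf("unknown season method '%s'; registered: %s", method,
                 paste(season_methods(), collapse = ", ")), call. = FALSE)
  get(method, envir = season_method_registry)(series, ...)
}

# --- intensity classes ----------------------------------------------------

#' Default clinical intensity cut-points
#'
#' Lower bounds (pollen grains m^-3) of the low/medium/high classes per
#' taxon; a day at or above a cut-point takes the higher class, below the
#' `low` cut-point the class is `nil`. The shipped values follow the common
#' three-source convention of stricter thresholds for grasses and herbs
#' than for trees; they are configuration, not measurement, and should be
#' replaced by the user's preferred national scheme where one applies.
#'
#' @return data frame with columns `taxon`, `low`, `medium`, `high`.
#' @export
default_intensity_table <- function() {
  tree <- c(low = 1, medium = 11, high = 101)
  herb <- c(low = 1, medium = 6, high = 31)
  rbind(
    data.frame(taxon = c("Corylus", "Alnus", "Betula", "Fraxinus", "Pinus"),
               low = tree["low"], medium = tree["medium"],
               high = tree["high"], row.names = NULL),
    data.frame(taxon = c("Poaceae", "Artemisia"), low = herb["low"],
               medium = herb["medium"], high = herb["high"],
               row.names = NULL))
}

#' Classify a daily concentration into an intensity level
#'
#' @param concentration daily pollen concentration (grains m^-3), vectorised.
#' @param taxon single taxon name, looked up in `table`.
#' @param table cut-point table as from [default_intensity_table()].
#' @return factor with levels `nil < low < medium < high`.
#' @export
classify_intensity <- function(concentration, taxon,
                               table = default_intensity_table()) {
  if (any(concentration < 0)) stop("negative concentration", call. = FALSE)
  row <- table[table$taxon == taxon, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("taxon '%s' not in intensity table; configured: %s", taxon,
                 paste(table$taxon, collapse = ", ")), call. = FALSE)
  cuts <- c(row$low, row$medium, row$high)
  if (any(diff(cuts) <= 0)) stop("cut-points must strictly increase",
                                 call. = FALSE)
  lab <- c("nil", "low", "medium", "high")
  idx <- findInterval(concentration, cuts) + 1L  # closed lower bounds
  factor(lab[idx], levels = lab, ordered = TRUE)
}

# --- reliability screening ------------------------------------------------

#' Reliability flags for a season start date
#'
#' Screens a defined season against the known failure modes of trap
#' operation: `LATE_START_CONC` if the first day of operation already
#' carried more than 4 pollen grains m^-3 (monitoring likely started after
#' the season began); `LATE_START_PHENO` if operation started fewer than 10
#' days before local flowering; `OP_AFTER_FLOWERING` if it started after
#' local flowering; `HIGH_MISSING` if more than 20% of days within
#' [SOS_P, EOS_P] were missing before imputation.
#'
#' @param series the original (pre-imputation) or imputed
#'   [daily_pollen_series()]; the pre-imputation mask is used when present.
#' @param season `season_params` for the series.
#' @param sos_f local flowering start (day-of-year) at the station pixel.
#' @param conc_threshold first-day concentration limit (default 4).
#' @param lead_days minimum operational lead before flowering (default 10).
#' @param missing_limit tolerated in-season missing fraction (default 0.20).
#' @return character vector of raised flags (possibly empty).
#' @export
check_sos_reliability <- function(series, season, sos_f,
                                  conc_threshold = 4, lead_days = 10,
                                  missing_limit = 0.20) {
  flags <- character(0)
  first_idx <- match(series$first_operation_doy, series$doy)
  first_conc <- if (!is.na(first_idx)) series$conc[first_idx] else NA_real_
  if (!is.na(first_conc) && first_conc > conc_threshold)
    flags <- c(flags, "LATE_START_CONC")
  if (series$first_operation_doy > sos_f - lead_days)
    flags <- c(flags, "LATE_START_PHENO")
  if (series$first_operation_doy > sos_f)
    flags <- c(flags, "OP_AFTER_FLOWERING")
  missing_doy <- series$premask_missing %||% series$doy[is.na(series$conc)]
  in_season <- series$doy >= season$sos_p & series$doy <= season$eos_p
  frac <- sum(missing_doy >= season$sos_p & missing_doy <= season$eos_p) /
    sum(in_season)
  if (is.finite(frac) && frac > missing_limit)
    flags <- c(flags, "HIGH_MISSING")
  flags
}

# --- trends ---------------------------------------------------------------

#' Linear trend of an annual series
#'
#' Ordinary least-squares regression of annual values on year; pairs with a
#' missing member are dropped.
#'
#' @param years numeric years.
#' @param values annual values (days or grains m^-3).
#' @return list of class `trend_result`: `slope` (units yr^-1), `p_value`
#'   (two-sided, of the slope), `n_years`.
#' @export
linear_trend <- function(years, values) {
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  if (length(years) < 3L)
    stop("at least 3 paired values required for a trend", call. = FALSE)
  fit <- stats::lm(values ~ years)
  sm <- suppressWarnings(summary(fit))$coefficients  # perfect fits are fine
  p <- if (nrow(sm) < 2L || is.na(sm["years", "Pr(>|t|)"])) NA_real_ else
    sm["years", "Pr(>|t|)"]
  structure(list(slope = unname(stats::coef(fit)["years"]), p_value = p,
                 n_years = length(years)), class = "trend_result")
}
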