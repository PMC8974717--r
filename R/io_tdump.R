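# Parser and writer for HYSPLIT trajectory endpoint ("tdump") text files.
# Only the fields the pipeline uses downstream (start time/place, point age,
# lat, lon, altitude) are required; additional diagnostic columns such as
# pressure are tolerated and ignored. Targets the whitespace-separated
# endpoint layout of HYSPLIT v4 and later.

tdump_tokens <- function(line) strsplit(trimws(line), "\\s+")[[1L]]

expand_year <- function(yy) {
  yy <- as.integer(yy)
  ifelse(yy >= 100L, yy, ifelse(yy < 50L, 2000L + yy, 1900L + yy))
}

#' Parse a HYSPLIT trajectory endpoint file
#'
#' Reads a "tdump" endpoint file: a header block (meteorological grid lines,
#' one start line per trajectory, diagnostic-variable line) followed by one
#' record per endpoint. Eight starts per day (3 h interval) and any number
#' of days are supported.
#'
#' @param path path to the endpoint file.
#' @return a list of [trajectory()] objects, points ordered by decreasing
#'   age. An empty endpoint section yields an empty list with a warning.
#'   Endpoints older than 72 h are kept and flagged on the trajectory.
#' @export
parse_tdump <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop(path, ": empty file", call. = FALSE)
  ngrids <- as.integer(tdump_tokens(lines[1L])[1L])
  if (is.na(ngrids) || ngrids < 0)
    stop(path, ": line 1: cannot read met-grid count", call. = FALSE)
  i <- 2L + ngrids                      # trajectory-count line
  hd <- tdump_tokens(lines[i])
  ntraj <- as.integer(hd[1L])
  if (is.na(ntraj) || ntraj < 1)
    stop(sprintf("%s: line %d: cannot read trajectory count", path, i),
         call. = FALSE)
  starts <- vector("list", ntraj)
  for (k in seq_len(ntraj)) {
    tk <- tdump_tokens(lines[i + k])
    if (length(tk) < 7L)
      stop(sprintf("%s: line %d: truncated trajectory-start line",
                   path, i + k), call. = FALSE)
    v <- as.numeric(tk[1:7])
    starts[[k]] <- list(
      time = ISOdatetime(expand_year(v[1L]), v[2L], v[3L], v[4L], 0, 0,
                         tz = "UTC"),
      lat = v[5L], lon = v[6L], alt = v[7L])
  }
  i <- i + ntraj + 1L                   # diagnostic-variable line
  first_rec <- i + 1L
  if (first_rec > length(lines) ||
      all(!nzchar(trimws(lines[first_rec:length(lines)])))) {
    warning(path, ": no endpoint records", call. = FALSE)
    return(list())
  }
  pts <- vector("list", ntraj)
  for (ln in first_rec:length(lines)) {
    if (!nzchar(trimws(lines[ln]))) next
    tk <- tdump_tokens(lines[ln])
    if (length(tk) < 12L)
      stop(sprintf("%s: line %d: truncated endpoint record", path, ln),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(tk))
    if (anyNA(v[1:12]))
      stop(sprintf("%s: line %d: unparseable endpoint record", path, ln),
           call. = FALSE)
    id <- as.integer(v[1L])
    if (id < 1L || id > ntraj)
      stop(sprintf("%s: line %d: unknown trajectory index %d", path, ln, id),
           call. = FALSE)
    pts[[id]] <- c(pts[[id]],
                   list(c(age = v[9L], lat = v[10L], lon = v[11L],
                          alt = v[12L])))
  }
  out <- vector("list", ntraj)
  for (k in seq_len(ntraj)) {
    if (is.null(pts[[k]]))
      stop(sprintf("%s: trajectory %d has no endpoints", path, k),
           call. = FALSE)
    m <- do.call(rbind, pts[[k]])
    m <- m[order(m[, "age"], decreasing = TRUE), , drop = FALSE]
    too_old <- m[, "age"] < -72
    if (any(too_old))
      warning(sprintf("%s: trajectory %d has %d endpoint(s) beyond 72 h",
                      path, k, sum(too_old)), call. = FALSE)
    out[[k]] <- trajectory(
      start_time = starts[[k]]$time, start_lat = starts[[k]]$lat,
      start_lon = starts[[k]]$lon, start_altitude_m = starts[[k]]$alt,
      points = data.frame(age_hours = m[, "age"], lat = m[, "lat"],
                          lon = m[, "lon"], altitude_m = m[, "alt"]))
  }
  out
}

#' Write trajectories in HYSPLIT endpoint layout
#'
#' Emits the whitespace-separated tdump layout that [parse_tdump()] reads
#' back, with a single pressure diagnostic column (zero-filled).
#'
#' @param trajectories a `trajectory` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tdump <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  n <- length(trajectories)
  if (!n) stop("no trajectories to write", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("     1     1",
               "    SYNT    99     1     1     0     0",
               sprintf("%6d BACKWARD OMEGA", n)), con)
  for (tr in trajectories) {
    tm <- as.POSIXlt(tr$start_time, tz = "UTC")
    writeLines(sprintf("%6d%6d%6d%6d %9.3f %9.3f %9.1f",
                       tm$year %% 100, tm$mon + 1L, tm$mday, tm$hour,
                       tr$start_lat, tr$start_lon, tr$start_altitude_m), con)
  }
  writeLines("     1 PRESSURE", con)
  for (k in seq_len(n)) {
    tr <- trajectories[[k]]
    for (j in seq_len(nrow(tr$points))) {
      p <- tr$points[j, ]
      tm <- as.POSIXlt(tr$start_time + p$age_hours * 3600, tz = "UTC")
      writeLines(sprintf(
        "%6d%6d%6d%6d%6d%6d%6d%6d %8.1f %9.4f %9.4f %9.1f %9.1f",
        k, 1L, tm$year %% 100, tm$mon + 1L, tm$mday, tm$hour, tm$min, 0L,
        p$age_hours, p$lat, p$lon, p$altitude_m, 0), con)
    }
  }
  invisible(path)
}
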