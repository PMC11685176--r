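# Reading, validating and writing GPS fix tables and ancestry tables.
#
# A track is one bird-year: the fixes an individual produced around one
# spring migration season. Fixes are stored time-sorted with duplicate
# timestamps collapsed to the first occurrence.

#' Construct a track object
#'
#' @param individual_id character scalar.
#' @param capture_state `"AR"` or `"TN"`; decides the departure latitude
#'   threshold used by [detect_departure()].
#' @param migration_year calendar year containing the track's 1 Feb - 31 May
#'   spring window.
#' @param fixes data frame with columns `timestamp` (POSIXct, UTC), `lon`,
#'   `lat` (WGS84 decimal degrees), at least 2 rows, strictly increasing
#'   timestamps.
#' @return An object of class `mig_track`.
#' @export
mig_track <- function(individual_id, capture_state, migration_year, fixes) {
  capture_state <- match.arg(capture_state, c("AR", "TN"))
  stopifnot(is.data.frame(fixes),
            all(c("timestamp", "lon", "lat") %in% names(fixes)))
  if (nrow(fixes) < 2) stop("a track needs at least 2 fixes")
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("fixes$timestamp must be POSIXct")
  attr(fixes$timestamp, "tzone") <- "UTC"
  if (is.unsorted(fixes$timestamp, strictly = TRUE))
    stop("fix timestamps must be strictly increasing")
  if (!all(is.finite(fixes$lon)) || !all(is.finite(fixes$lat)) ||
      any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180))
    stop("fix coordinates out of range")
  structure(
    list(individual_id = as.character(individual_id),
         capture_state = capture_state,
         migration_year = as.integer(migration_year),
         fixes = fixes[, c("timestamp", "lon", "lat")]),
    class = "mig_track")
}

#' @export
print.mig_track <- function(x, ...) {
  cat(sprintf("<mig_track> %s (%s), spring %d: %d fixes, %s .. %s\n",
              x$individual_id, x$capture_state, x$migration_year,
              nrow(x$fixes),
              format(min(x$fixes$timestamp), "%Y-%m-%d"),
              format(max(x$fixes$timestamp), "%Y-%m-%d")))
  invisible(x)
}

# Spring seasons run Feb-May; fixes from Aug-Dec are attached to the
# following calendar year's spring so that a track spanning a New Year
# (winter capture -> spring migration) stays one unit.
migration_year_of <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  yr <- lt$year + 1900L
  ifelse(lt$mon + 1L >= 8L, yr + 1L, yr)
}

#' Read GPS fix tables into tracks
#'
#' Reads a Movebank-flavored CSV of GPS fixes, validates rows, and groups
#' them into one [mig_track()] per individual and migration year. Rows with
#' unparseable timestamps or out-of-range coordinates are dropped and
#' counted; duplicate timestamps within a bird-year keep the first
#' occurrence. A validation report is attached as attribute `"report"`.
#'
#' @param path CSV file of fixes.
#' @param schema named character vector mapping the roles `id`, `timestamp`,
#'   `lon`, `lat`, `state` to column names in the file.
#' @return List of `mig_track` objects, attribute `report` a list with
#'   counts of dropped rows per reason.
#' @export
read_tracks <- function(path,
                        schema = c(id = "individual_id",
                                   timestamp = "timestamp",
                                   lon = "lon", lat = "lat",
                                   state = "capture_state")) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("id", "timestamp", "lon", "lat", "state")
  if (!all(need %in% names(schema)))
    stop("schema must name columns for: ", paste(need, collapse = ", "))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  n0 <- nrow(raw)
  ts <- as.POSIXct(raw[[schema[["timestamp"]]]], tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(raw[[schema[["lon"]]]]))
  lat <- suppressWarnings(as.numeric(raw[[schema[["lat"]]]]))
  bad_time <- is.na(ts)
  bad_coord <- !bad_time & (!is.finite(lon) | !is.finite(lat) |
                            abs(lat) > 90 | abs(lon) > 180)
  bad <- bad_time | bad_coord
  if (n0 > 0 && sum(bad) / n0 > 0.10)
    stop(sprintf("%d of %d rows invalid (>10%%); refusing to proceed",
                 sum(bad), n0))
  keep <- !bad
  df <- data.frame(id = as.character(raw[[schema[["id"]]]])[keep],
                   timestamp = ts[keep], lon = lon[keep], lat = lat[keep],
                   state = as.character(raw[[schema[["state"]]]])[keep],
                   stringsAsFactors = FALSE)
  df$myear <- migration_year_of(df$timestamp)
  df <- df[order(df$id, df$myear, df$timestamp), ]

  n_dup <- 0L
  tracks <- list()
  for (key in unique(paste(df$id, df$myear, sep = "\r"))) {
    sub <- df[paste(df$id, df$myear, sep = "\r") == key, ]
    dup <- duplicated(sub$timestamp)
    n_dup <- n_dup + sum(dup)
    sub <- sub[!dup, ]
    if (nrow(sub) < 2) next
    tracks[[length(tracks) + 1L]] <-
      mig_track(sub$id[1], sub$state[1], sub$myear[1],
                sub[, c("timestamp", "lon", "lat")])
  }
  attr(tracks, "report") <- list(
    rows_read = n0,
    rows_bad_timestamp = sum(bad_time),
    rows_bad_coordinate = sum(bad_coord),
    rows_duplicate_timestamp = n_dup,
    tracks = length(tracks))
  tracks
}

#' Write tracks back to a fix CSV
#'
#' Inverse of [read_tracks()] on valid data (round-trip identity).
#'
#' @param tracks list of `mig_track` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(individual_id = tr$individual_id,
               timestamp = format(tr$fixes$timestamp, "%Y-%m-%d %H:%M:%S",
                                  tz = "UTC"),
               lon = tr$fixes$lon, lat = tr$fixes$lat,
               capture_state = tr$capture_state,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-individual ancestry table
#'
#' Two-column CSV: individual id and game-farm ancestry fraction in
#' \[0, 1\] (one minus the wild assignment probability Q).
#'
#' @param path CSV path with columns `individual_id`, `gamefarm_fraction`.
#' @return data frame with those two columns.
#' @export
read_ancestry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "gamefarm_fraction") %in% names(df)))
    stop("ancestry table needs columns individual_id, gamefarm_fraction")
  f <- df$gamefarm_fraction
  if (any(!is.finite(f)) || any(f < 0 | f > 1))
    stop("gamefarm_fraction must lie in [0, 1]")
  df$individual_id <- as.character(df$individual_id)
  df[, c("individual_id", "gamefarm_fraction")]
}

#' Step lengths and time gaps along a track
#'
#' Great-circle distance and elapsed time between consecutive fixes.
#'
#' @param track a `mig_track`.
#' @return data frame with `n_fixes - 1` rows: `step_km` (>= 0) and
#'   `dt_hours` (> 0).
#' @export
step_lengths <- function(track) {
  stopifnot(inherits(track, "mig_track"))
  fx <- track$fixes
  n <- nrow(fx)
  if (n < 2) stop("a track needs at least 2 fixes")
  data.frame(
    step_km = haversine_km(fx$lon[-n], fx$lat[-n], fx$lon[-1], fx$lat[-1]),
    dt_hours = as.numeric(difftime(fx$timestamp[-1], fx$timestamp[-n],
                                   units = "hours")))
}
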