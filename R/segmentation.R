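# Spring-migration segmentation: step classification, departure detection by
# state-specific latitude threshold, residency establishment (>=10-day dwell
# in a 25-km-radius circle north of 43 N), stopovers (>=24-h dwells between
# departure and residency), and the eight per-track phenology metrics.

#' Segmentation rules
#'
#' Thresholds and buffers controlling track segmentation. Defaults follow the
#' study design for mallards wintering in Arkansas/Tennessee: departure is the
#' first fix strictly above the capture state's threshold latitude (the
#' northernmost January position per state), restricted to 1 Feb - 31 May;
#' residency is a dwell of at least `residency_min_days` inside a circle of
#' `residency_radius_km` (a "50-km-diameter" buffer) anchored north of 43 N;
#' stopovers are dwells of at least `stopover_min_hours` in a
#' `stopover_radius_km` circle strictly between departure and residency.
#'
#' @param departure_lat_AR,departure_lat_TN departure latitude thresholds
#'   (decimal degrees) for Arkansas and Tennessee captures.
#' @param season_start_month,season_start_day,season_end_month,season_end_day
#'   inclusive calendar window for legal departures.
#' @param residency_lat_min minimum latitude of a residency anchor fix.
#' @param residency_radius_km dwell circle radius for residency.
#' @param residency_min_days minimum residency dwell length, days.
#' @param stopover_radius_km dwell circle radius for stopovers.
#' @param stopover_min_hours minimum stopover dwell, hours.
#' @param wetland_max_km,migration_min_km step-class boundaries, km.
#' @return A list of class `segmentation_rules`.
#' @export
segmentation_rules <- function(departure_lat_AR = 35.904,
                               departure_lat_TN = 36.982,
                               season_start_month = 2L, season_start_day = 1L,
                               season_end_month = 5L, season_end_day = 31L,
                               residency_lat_min = 43.0,
                               residency_radius_km = 25,
                               residency_min_days = 10,
                               stopover_radius_km = 25,
                               stopover_min_hours = 24,
                               wetland_max_km = 0.25,
                               migration_min_km = 50) {
  stopifnot(wetland_max_km > 0, migration_min_km > wetland_max_km,
            residency_radius_km > 0, residency_min_days > 0,
            stopover_radius_km > 0, stopover_min_hours > 0)
  structure(list(departure_lat_AR = departure_lat_AR,
                 departure_lat_TN = departure_lat_TN,
                 season_start_month = season_start_month,
                 season_start_day = season_start_day,
                 season_end_month = season_end_month,
                 season_end_day = season_end_day,
                 residency_lat_min = residency_lat_min,
                 residency_radius_km = residency_radius_km,
                 residency_min_days = residency_min_days,
                 stopover_radius_km = stopover_radius_km,
                 stopover_min_hours = stopover_min_hours,
                 wetland_max_km = wetland_max_km,
                 migration_min_km = migration_min_km),
            class = "segmentation_rules")
}

#' Classify step lengths into movement modes
#'
#' Steps below `wetland_max_km` (default 0.25 km) are within-wetland
#' movements, steps of at least `migration_min_km` (default 50 km) are
#' migration events, everything between is local-regional movement. Both
#' lower bounds are inclusive: 0.25 km is local-regional, 50 km is migration.
#'
#' @param step_km numeric vector of step lengths (km, >= 0).
#' @param rules a [segmentation_rules()] object.
#' @return factor with levels `wetland`, `local_regional`, `migration`.
#' @export
classify_step <- function(step_km, rules = segmentation_rules()) {
  stopifnot(all(step_km >= 0))
  cls <- ifelse(step_km < rules$wetland_max_km, "wetland",
         ifelse(step_km >= rules$migration_min_km, "migration",
                "local_regional"))
  factor(cls, levels = c("wetland", "local_regional", "migration"))
}

#' Natural breaks of the log step-length density
#'
#' Estimates a Gaussian-kernel density of log10 step lengths (Silverman's
#' rule by default) and returns the antilog of its interior local minima, in
#' ascending order. These "natural breaks" are a diagnostic for the
#' separation of movement modes; classification itself uses the fixed
#' thresholds in [classify_step()].
#'
#' @param step_km positive step lengths, km; zeros are dropped with a
#'   warning, and at least 100 positive steps are required.
#' @param bw bandwidth rule or value passed to [stats::density()].
#' @param n grid size for the density estimate.
#' @return numeric vector of break values in km (possibly empty).
#' @export
log_step_density_breaks <- function(step_km, bw = "nrd0", n = 512) {
  step_km <- step_km[is.finite(step_km)]
  if (any(step_km == 0)) {
    warning("dropping zero step lengths before log transform")
    step_km <- step_km[step_km > 0]
  }
  if (any(step_km < 0)) stop("step lengths must be non-negative")
  if (length(step_km) < 100)
    stop("need at least 100 positive steps for a stable density estimate")
  d <- stats::density(log10(step_km), bw = bw, n = n)
  y <- d$y
  i <- 2:(length(y) - 1)
  minima <- i[y[i] < y[i - 1] & y[i] <= y[i + 1]]
  10^d$x[minima]
}

season_window <- function(year, rules) {
  c(start = as.POSIXct(sprintf("%04d-%02d-%02d 00:00:00", year,
                               rules$season_start_month,
                               rules$season_start_day), tz = "UTC"),
    end = as.POSIXct(sprintf("%04d-%02d-%02d 23:59:59", year,
                             rules$season_end_month,
                             rules$season_end_day), tz = "UTC"))
}

#' Detect spring migration departure
#'
#' Departure is the first fix whose latitude strictly exceeds the capture
#' state's threshold. Departures dated before 1 February or after 31 May of
#' the migration year are excluded (both endpoints are legal departure
#' dates).
#'
#' @param track a `mig_track`.
#' @param rules a [segmentation_rules()] object.
#' @return list with `status` (`"ok"`, `"no_departure"`, or
#'   `"excluded_by_season"`) and `index` (fix index or `NA`).
#' @export
detect_departure <- function(track, rules = segmentation_rules()) {
  thr <- switch(track$capture_state,
                AR = rules$departure_lat_AR,
                TN = rules$departure_lat_TN)
  idx <- which(track$fixes$lat > thr)
  if (!length(idx)) return(list(status = "no_departure", index = NA_integer_))
  i <- idx[1]
  w <- season_window(track$migration_year, rules)
  t_i <- track$fixes$timestamp[i]
  if (t_i < w["start"] || t_i > w["end"])
    return(list(status = "excluded_by_season", index = i))
  list(status = "ok", index = i)
}

#' Detect residency establishment
#'
#' Scanning fixes after departure in time order, residency is anchored at
#' the earliest fix above `residency_lat_min` such that every fix within the
#' following `residency_min_days` stays inside `residency_radius_km` of the
#' anchor, and the track record extends at least that long past the anchor
#' (tracks ending earlier return `no_residency` rather than a guess).
#'
#' @param track a `mig_track`.
#' @param departure_idx index returned by [detect_departure()].
#' @param rules a [segmentation_rules()] object.
#' @return list with `status` (`"ok"` or `"no_residency"`) and `index`.
#' @export
detect_residency <- function(track, departure_idx,
                             rules = segmentation_rules()) {
  fx <- track$fixes
  n <- nrow(fx)
  t_end <- fx$timestamp[n]
  win <- rules$residency_min_days * 86400
  for (i in seq(departure_idx, n)) {
    if (fx$lat[i] <= rules$residency_lat_min) next
    t_i <- fx$timestamp[i]
    if (as.numeric(t_end) - as.numeric(t_i) < win) next
    j <- which(fx$timestamp >= t_i &
               fx$timestamp <= t_i + win)
    d <- haversine_km(fx$lon[i], fx$lat[i], fx$lon[j], fx$lat[j])
    if (all(d <= rules$residency_radius_km))
      return(list(status = "ok", index = i))
  }
  list(status = "no_residency", index = NA_integer_)
}

#' Detect stopovers between departure and residency
#'
#' Greedy forward scan over the fixes strictly between the departure fix and
#' the residency anchor: a candidate dwell opens at the first unconsumed fix
#' and extends over consecutive fixes while they stay within
#' `stopover_radius_km` of the anchor fix. If the elapsed time between the
#' first and last member fix reaches `stopover_min_hours` the dwell is
#' emitted as a stopover and its fixes are consumed; otherwise the scan
#' advances one fix. Overlapping alternatives resolve to the earliest
#' anchor.
#'
#' @param track a `mig_track`.
#' @param departure_idx,residency_idx segmentation endpoints.
#' @param rules a [segmentation_rules()] object.
#' @return data frame, one row per stopover: `anchor_idx`, `first_idx`,
#'   `last_idx`, `start`, `end`, `duration_hours`, `lon`, `lat`.
#' @export
detect_stopovers <- function(track, departure_idx, residency_idx,
                             rules = segmentation_rules()) {
  fx <- track$fixes
  empty <- data.frame(anchor_idx = integer(), first_idx = integer(),
                      last_idx = integer(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_hours = numeric(),
                      lon = numeric(), lat = numeric())
  lo <- departure_idx + 1L
  hi <- residency_idx - 1L
  if (hi < lo) return(empty)
  out <- list()
  a <- lo
  while (a <= hi) {
    d <- haversine_km(fx$lon[a], fx$lat[a], fx$lon[a:hi], fx$lat[a:hi])
    run <- which(d > rules$stopover_radius_km)
    last <- if (length(run)) a + run[1] - 2L else hi
    dur <- as.numeric(difftime(fx$timestamp[last], fx$timestamp[a],
                               units = "hours"))
    if (dur >= rules$stopover_min_hours) {
      out[[length(out) + 1L]] <- data.frame(
        anchor_idx = a, first_idx = a, last_idx = last,
        start = fx$timestamp[a], end = fx$timestamp[last],
        duration_hours = dur, lon = fx$lon[a], lat = fx$lat[a])
      a <- last + 1L
    } else {
      a <- a + 1L
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Segment a track into migration phases
#'
#' Runs departure, residency and stopover detection and classifies steps.
#'
#' @param track a `mig_track`.
#' @param rules a [segmentation_rules()] object.
#' @return An object of class `segmented_track`: the source track plus
#'   `status` (`complete`, `no_departure`, `excluded_by_season`,
#'   `no_residency`), departure/residency indices and times, stopover table
#'   and per-step classes.
#' @export
segment_track <- function(track, rules = segmentation_rules()) {
  steps <- step_lengths(track)
  res <- list(track = track, rules = rules,
              step_class = classify_step(steps$step_km, rules),
              status = NA_character_,
              departure_idx = NA_integer_, departure_time = NA,
              residency_idx = NA_integer_, residency_time = NA,
              residency_lat = NA_real_, stopovers = NULL)
  dep <- detect_departure(track, rules)
  if (dep$status != "ok") {
    res$status <- dep$status
    class(res) <- "segmented_track"
    return(res)
  }
  res$departure_idx <- dep$index
  res$departure_time <- track$fixes$timestamp[dep$index]
  resd <- detect_residency(track, dep$index, rules)
  if (resd$status != "ok") {
    res$status <- "no_residency"
    class(res) <- "segmented_track"
    return(res)
  }
  res$residency_idx <- resd$index
  res$residency_time <- track$fixes$timestamp[resd$index]
  res$residency_lat <- track$fixes$lat[resd$index]
  res$stopovers <- detect_stopovers(track, dep$index, resd$index, rules)
  res$status <- "complete"
  class(res) <- "segmented_track"
  res
}

#' @export
print.segmented_track <- function(x, ...) {
  cat(sprintf("<segmented_track> %s spring %d: %s\n",
              x$track$individual_id, x$track$migration_year, x$status))
  if (x$status == "complete")
    cat(sprintf("  departure %s | residency %s at %.3f N | %d stopover(s)\n",
                format(x$departure_time, "%Y-%m-%d %H:%M"),
                format(x$residency_time, "%Y-%m-%d %H:%M"),
                x$residency_lat, nrow(x$stopovers)))
  invisible(x)
}

doy_of <- function(timestamp) {
  as.POSIXlt(timestamp, tz = "UTC")$yday + 1L
}

#' Derive the per-track phenology record
#'
#' Computes the eight migration-behavior responses from a complete
#' segmentation: departure and arrival day-of-year, arrival latitude, total
#' migration distance (sum of step lengths from the departure fix to the
#' residency fix), migration duration (days), stopover count, total stopover
#' duration (hours; zero imputed when the bird never stopped), and distance
#' to the nearest urban area at the arrival location (if polygons are
#' supplied).
#'
#' @param segmented a `segmented_track` with `status == "complete"`.
#' @param gamefarm_fraction the individual's game-farm ancestry fraction.
#' @param urban optional [urban_areas()] polygons for the urban-distance
#'   response; `NA` is recorded when absent.
#' @return one-row data frame (a phenology record).
#' @export
compute_phenology <- function(segmented, gamefarm_fraction, urban = NULL) {
  stopifnot(inherits(segmented, "segmented_track"))
  if (segmented$status != "complete")
    stop("phenology requires a complete segmentation, got: ",
         segmented$status)
  fx <- segmented$track$fixes
  i0 <- segmented$departure_idx
  i1 <- segmented$residency_idx
  dist_km <- if (i1 > i0) {
    ii <- i0:(i1 - 1)
    sum(haversine_km(fx$lon[ii], fx$lat[ii], fx$lon[ii + 1], fx$lat[ii + 1]))
  } else 0
  dur_days <- as.numeric(difftime(segmented$residency_time,
                                  segmented$departure_time, units = "days"))
  st <- segmented$stopovers
  d_urb <- if (is.null(urban)) NA_real_ else
    distance_to_urban(fx$lon[i1], fx$lat[i1], urban)
  data.frame(
    individual_id = segmented$track$individual_id,
    migration_year = segmented$track$migration_year,
    departure_doy = doy_of(segmented$departure_time),
    arrival_doy = doy_of(segmented$residency_time),
    arrival_lat = segmented$residency_lat,
    migration_distance_km = dist_km,
    migration_duration_days = dur_days,
    n_stopovers = nrow(st),
    stopover_duration_h = if (nrow(st)) sum(st$duration_hours) else 0,
    distance_to_urban_km = d_urb,
    gamefarm_fraction = gamefarm_fraction,
    stringsAsFactors = FALSE)
}

#' Segment a cohort of tracks into a phenology table
#'
#' Applies [segment_track()] and [compute_phenology()] to every track,
#' joining per-individual ancestry.
#'
#' @param tracks list of `mig_track` objects.
#' @param ancestry data frame from [read_ancestry()] (or
#'   [simulate_ancestry()]).
#' @param rules a [segmentation_rules()] object.
#' @param urban optional [urban_areas()] polygons.
#' @return list with `phenology` (one row per complete track) and `status`
#'   (one row per track: id, year, segmentation status).
#' @export
segment_cohort <- function(tracks, ancestry, rules = segmentation_rules(),
                           urban = NULL) {
  anc <- stats::setNames(ancestry$gamefarm_fraction, ancestry$individual_id)
  phen <- list()
  status <- list()
  for (tr in tracks) {
    if (!tr$individual_id %in% names(anc))
      stop("no ancestry record for individual ", tr$individual_id)
    seg <- segment_track(tr, rules)
    status[[length(status) + 1L]] <- data.frame(
      individual_id = tr$individual_id, migration_year = tr$migration_year,
      status = seg$status, stringsAsFactors = FALSE)
    if (seg$status == "complete")
      phen[[length(phen) + 1L]] <-
        compute_phenology(seg, anc[[tr$individual_id]], urban)
  }
  list(phenology = if (length(phen)) do.call(rbind, phen) else NULL,
       status = do.call(rbind, status))
}
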