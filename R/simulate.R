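# Synthetic GPS cohorts with known effect sizes.
#
# The generator emulates mallards wintering near 35-37 N that depart between
# 1 Feb and 31 May, migrate north in >= 50-km flights interleaved with
# >= 24-h stopovers, and establish >= 10-day residency above 43 N. Departure
# day, arrival day, arrival latitude and total migration distance are linear
# in 2-SD-standardized game-farm ancestry, so the same coefficients the
# hierarchical models estimate are known truth here. Tracks are laid out on
# a 2-h fix grid so that segmentation recovers the latent values exactly.

#' Generative truth for a synthetic cohort
#'
#' Effect sizes are per unit of 2-SD-standardized ancestry, on the response's
#' own scale (days, days, degrees latitude, km), matching the scale on which
#' the hierarchical models report coefficients. Defaults reproduce the
#' study conditions: a cohort of 296 birds (41 with two springs, 337 tracks),
#' roughly 10% hybrids with game-farm fractions up to 0.23, and ancestry
#' effects of +1.62 d (departure), +2.02 d (arrival), -0.33 deg (arrival
#' latitude) and -70.77 km (migration distance); stopover count/duration and
#' urban distance carry no ancestry effect.
#'
#' @param beta_departure,beta_arrival,beta_latitude,beta_distance ancestry
#'   effects (days, days, degrees, km per standardized unit).
#' @param sigma_departure,sigma_arrival,sigma_latitude,sigma_distance
#'   residual SDs of the four structured responses.
#' @param sd_individual,sd_year random-intercept SDs (days), shared by the
#'   two timing responses.
#' @param hybrid_prob proportion of hybrids in the cohort.
#' @param max_gamefarm upper bound of the game-farm ancestry fraction.
#' @param n_individuals cohort size; `repeat_fraction` of them contribute a
#'   second spring.
#' @param repeat_fraction fraction of individuals tracked for two springs.
#' @param years candidate migration years.
#' @param prop_AR share of birds captured in Arkansas (rest Tennessee).
#' @param baseline_departure_doy,baseline_arrival_doy mean departure/arrival
#'   day-of-year at average ancestry.
#' @param baseline_arrival_lat,baseline_distance_km mean arrival latitude
#'   (deg N) and migration distance (km).
#' @param stopover_rate Poisson mean of the per-track stopover count.
#' @param stopover_dur_h range (h) of individual stopover dwell draws.
#' @param fix_interval_h GPS fix interval, hours.
#' @param winter_days days of pre-departure wintering fixes emitted.
#' @param residency_days days of post-arrival residency fixes emitted.
#' @param leg_km_max maximum planned flight-leg length, km.
#' @param seed integer RNG seed consumed by [simulate_cohort()].
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(beta_departure = 1.62,
                             beta_arrival = 2.02,
                             beta_latitude = -0.33,
                             beta_distance = -70.77,
                             sigma_departure = 8,
                             sigma_arrival = 8,
                             sigma_latitude = 1.2,
                             sigma_distance = 120,
                             sd_individual = 2,
                             sd_year = 1,
                             hybrid_prob = 0.10,
                             max_gamefarm = 0.23,
                             n_individuals = 296L,
                             repeat_fraction = 41 / 296,
                             years = 2019:2023,
                             prop_AR = 95 / 296,
                             baseline_departure_doy = 65,
                             baseline_arrival_doy = 95,
                             baseline_arrival_lat = 47,
                             baseline_distance_km = 1600,
                             stopover_rate = 1.5,
                             stopover_dur_h = c(24, 96),
                             fix_interval_h = 2,
                             winter_days = 6,
                             residency_days = 12,
                             leg_km_max = 250,
                             seed = 1L) {
  stopifnot(sd_individual >= 0, sd_year >= 0,
            hybrid_prob >= 0, hybrid_prob <= 1,
            max_gamefarm > 0, max_gamefarm <= 1,
            n_individuals >= 1, fix_interval_h > 0,
            stopover_dur_h[1] >= 24)
  structure(as.list(environment()), class = "simulation_truth")
}

#' Simulate per-individual ancestry fractions
#'
#' With probability `1 - hybrid_prob` a bird is genetically wild (fraction
#' drawn uniformly below 0.02); otherwise it is a late-generation backcross
#' with fraction uniform on (0.02, `max_gamefarm`].
#'
#' @param n number of individuals.
#' @param hybrid_prob proportion of hybrids.
#' @param max_gamefarm upper ancestry bound for hybrids.
#' @param ids individual ids.
#' @return data frame: `individual_id`, `gamefarm_fraction`.
#' @export
simulate_ancestry <- function(n, hybrid_prob = 0.10, max_gamefarm = 0.23,
                              ids = sprintf("bird%04d", seq_len(n))) {
  stopifnot(n >= 1, hybrid_prob >= 0, hybrid_prob <= 1,
            max_gamefarm > 0.02, max_gamefarm <= 1)
  hybrid <- stats::runif(n) < hybrid_prob
  frac <- ifelse(hybrid,
                 stats::runif(n, 0.02, max_gamefarm),
                 stats::runif(n, 0, 0.02))
  data.frame(individual_id = ids, gamefarm_fraction = frac,
             stringsAsFactors = FALSE)
}

state_threshold <- function(state) {
  switch(state, AR = 35.904, TN = 36.982)
}

# Jittered position around a center: short within-wetland displacements most
# of the time, occasional local-regional excursions up to max_excursion_km.
jitter_positions <- function(n, lon, lat, p_wetland = 0.7,
                             max_excursion_km = 8) {
  r <- ifelse(stats::runif(n) < p_wetland,
              stats::runif(n, 0.01, 0.2),
              stats::runif(n, 0.3, max_excursion_km))
  b <- stats::runif(n, 0, 360)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) out[i, ] <- move_point(lon, lat, b[i], r[i])
  out
}

grid_h <- function(x, interval) interval * round(x / interval)

# Longitude offset (degrees) such that a leg from latitude lat_a to lat_b
# has great-circle length exactly L km (inverse haversine in the longitude
# term). Requires L >= the meridian distance between the two latitudes.
leg_dlon <- function(lat_a, lat_b, L) {
  rad <- pi / 180
  s <- sin(L / (2 * EARTH_RADIUS_KM))^2 - sin((lat_b - lat_a) * rad / 2)^2
  s <- max(s, 0)
  2 * asin(min(1, sqrt(s / (cos(lat_a * rad) * cos(lat_b * rad))))) / rad
}

#' Simulate one migration track
#'
#' Emits a full GPS fix series on a regular grid: wintering jitter south of
#' the state departure threshold, a first >= 50-km northward flight at
#' 08:00 UTC on the latent departure day, alternating-bearing flight legs
#' (each >= 50 km) interleaved with stopovers (>= 24-h dwells within 25 km,
#' placed below 42.5 N) and sub-24-h rests, arrival at the latent terminal
#' latitude, and a 12-day residency dwell. The returned latent values are
#' the realized ones (arrival time and stopover count are renegotiated in
#' the rare case the linear targets are infeasible), so segmentation output
#' matches them exactly at fix resolution.
#'
#' @param individual_id id string.
#' @param z 2-SD-standardized ancestry of this bird (cohort-level scaling).
#' @param u_ind,v_year individual and year random intercepts (days).
#' @param capture_state `"AR"` or `"TN"`.
#' @param year migration year.
#' @param truth a [simulation_truth()] object.
#' @return list with `track` (a [mig_track()]) and `latent` (one-row data
#'   frame of true departure/arrival day-of-year, arrival latitude, stopover
#'   count and total duration, and the planned distance target).
#' @export
simulate_track <- function(individual_id, z, u_ind, v_year, capture_state,
                           year, truth) {
  int <- truth$fix_interval_h
  thr <- state_threshold(capture_state)
  site_lon <- switch(capture_state, AR = -91.1, TN = -88.9) +
    stats::runif(1, -0.3, 0.3)
  site_lat <- thr - 0.45 + stats::runif(1, -0.05, 0.05)

  # latent departure day, clamped to the legal season window
  doy_feb1 <- 32L
  doy_may31 <- doy_of(as.POSIXct(sprintf("%d-05-31", year), tz = "UTC"))
  dep_doy <- round(truth$baseline_departure_doy + truth$beta_departure * z +
                   u_ind + v_year + stats::rnorm(1, 0, truth$sigma_departure))
  dep_doy <- min(max(dep_doy, doy_feb1), doy_may31)
  jan1 <- as.POSIXct(sprintf("%d-01-01 08:00:00", year), tz = "UTC")
  dep_t <- jan1 + (dep_doy - 1) * 86400

  # latent arrival target (renegotiated below if infeasible)
  arr_doy_target <- truth$baseline_arrival_doy + truth$beta_arrival * z +
    u_ind + v_year + stats::rnorm(1, 0, truth$sigma_arrival)
  gap_h <- grid_h(max((arr_doy_target - dep_doy) * 24, int), int)

  # latent terminal latitude and distance target
  lat_T <- truth$baseline_arrival_lat + truth$beta_latitude * z +
    stats::rnorm(1, 0, truth$sigma_latitude)
  lat_T <- max(lat_T, 43.2)
  dep_pos <- move_point(site_lon, site_lat, 0, 60)  # first flight, >= 50 km
  d_north <- haversine_km(dep_pos[1], dep_pos[2], dep_pos[1], lat_T)
  d_tgt <- truth$baseline_distance_km + truth$beta_distance * z +
    stats::rnorm(1, 0, truth$sigma_distance)
  d_tgt <- max(d_tgt, d_north * 1.02)

  k <- stats::rpois(1, truth$stopover_rate)

  # lay out legs on exact latitude waypoints, alternating the east-west
  # longitude offset so every leg has length exactly L and the flight path
  # sums to d_tgt, terminating exactly at lat_T; grow the leg count if more
  # below-42.5N stopover slots are needed
  n_legs <- max(ceiling(d_tgt / truth$leg_km_max), 2L)
  n_legs_max <- max(floor(d_tgt / 60), 2L)
  repeat {
    L <- d_tgt / n_legs
    lat_w <- dep_pos[2] + (seq_len(n_legs) / n_legs) * (lat_T - dep_pos[2])
    pos <- matrix(NA_real_, n_legs, 2)
    lon_cur <- dep_pos[1]
    lat_cur <- dep_pos[2]
    for (i in seq_len(n_legs)) {
      dlon <- leg_dlon(lat_cur, lat_w[i], L)
      lon_cur <- lon_cur + dlon * (if (i %% 2 == 1) 1 else -1)
      lat_cur <- lat_w[i]
      pos[i, ] <- c(lon_cur, lat_cur)
    }
    eligible <- which(pos[seq_len(n_legs - 1), 2] < 42.5)
    flight_h <- n_legs * int
    dwell_needed <- gap_h - flight_h
    if (dwell_needed < 0) { gap_h <- flight_h; dwell_needed <- 0 }
    # renegotiate k against the available dwell time and slots; a zero
    # stopover rate is honored (arrival is realized earlier instead)
    if (truth$stopover_rate > 0 && k == 0 &&
        dwell_needed > (n_legs - 1) * 20)
      k <- ceiling((dwell_needed - (n_legs - 1) * 10) / 240)
    k <- min(k, floor(dwell_needed / 26))
    k <- max(k, 0L)
    if (k <= length(eligible)) break
    if (n_legs + 2L > n_legs_max) { k <- length(eligible); break }
    n_legs <- n_legs + 2L
  }

  stop_slots <- if (k > 0)
    sort(eligible[sample.int(length(eligible), k)]) else integer()
  rest_slots <- setdiff(seq_len(n_legs - 1), stop_slots)
  s_dur <- if (k > 0)
    grid_h(stats::runif(k, truth$stopover_dur_h[1], truth$stopover_dur_h[2]),
           int)
  else numeric()
  s_dur <- pmax(s_dur, 24)
  r_dur <- if (length(rest_slots))
    grid_h(stats::runif(length(rest_slots), 0, 20), int) else numeric()

  # balance dwell time so arrival lands on the latent target when feasible
  diff_h <- dwell_needed - sum(s_dur) - sum(r_dur)
  if (diff_h > 0) {
    if (k > 0) {
      units <- diff_h / int
      add <- rep(floor(units / k), k)
      extra <- units - sum(add)
      if (extra > 0) add[seq_len(extra)] <- add[seq_len(extra)] + 1
      s_dur <- s_dur + add * int
    } else if (length(r_dur)) {
      # greedy top-up on the grid, each rest capped below 24 h
      i <- 1
      while (diff_h > 0 && i <= length(r_dur)) {
        step <- min(22 - r_dur[i], diff_h)
        step <- floor(step / int) * int
        r_dur[i] <- r_dur[i] + step
        diff_h <- diff_h - step
        i <- i + 1
      }
    }
  } else if (diff_h < 0) {
    need <- -diff_h
    for (i in seq_along(r_dur)) {
      cut <- min(r_dur[i], need)
      r_dur[i] <- r_dur[i] - cut
      need <- need - cut
      if (need <= 0) break
    }
    if (need > 0) for (i in seq_along(s_dur)) {
      cut <- min(s_dur[i] - 24, need)
      s_dur[i] <- s_dur[i] - cut
      need <- need - cut
      if (need <= 0) break
    }
  }

  # emit fixes
  fixes <- list()
  w_times <- seq(dep_t - truth$winter_days * 86400, dep_t - int * 3600,
                 by = int * 3600)
  wp <- jitter_positions(length(w_times), site_lon, site_lat)
  fixes[[1]] <- data.frame(timestamp = w_times, lon = wp[, 1], lat = wp[, 2])
  fixes[[2]] <- data.frame(timestamp = dep_t, lon = dep_pos[1],
                           lat = dep_pos[2])
  t_cur <- dep_t
  dwell_at <- function(slot) {
    if (slot %in% stop_slots) s_dur[match(slot, stop_slots)]
    else r_dur[match(slot, rest_slots)]
  }
  for (i in seq_len(n_legs)) {
    t_cur <- t_cur + int * 3600
    fixes[[length(fixes) + 1L]] <-
      data.frame(timestamp = t_cur, lon = pos[i, 1], lat = pos[i, 2])
    if (i < n_legs) {
      d <- dwell_at(i)
      if (d >= int) {
        dt <- seq(int, d, by = int) * 3600
        dp <- jitter_positions(length(dt), pos[i, 1], pos[i, 2],
                               p_wetland = 0.85, max_excursion_km = 1.5)
        fixes[[length(fixes) + 1L]] <-
          data.frame(timestamp = t_cur + dt, lon = dp[, 1], lat = dp[, 2])
        t_cur <- t_cur + d * 3600
      }
    }
  }
  arr_t <- t_cur
  res_dt <- seq(int, truth$residency_days * 24, by = int) * 3600
  rp <- jitter_positions(length(res_dt), pos[n_legs, 1], pos[n_legs, 2],
                         p_wetland = 0.85, max_excursion_km = 1.5)
  fixes[[length(fixes) + 1L]] <-
    data.frame(timestamp = arr_t + res_dt, lon = rp[, 1], lat = rp[, 2])

  fx <- do.call(rbind, fixes)
  track <- mig_track(individual_id, capture_state, year, fx)
  latent <- data.frame(
    individual_id = individual_id, migration_year = year,
    capture_state = capture_state,
    departure_doy = dep_doy,
    arrival_doy = doy_of(arr_t),
    arrival_time = arr_t,
    departure_time = dep_t,
    arrival_lat = pos[n_legs, 2],
    n_stopovers = length(stop_slots),
    stopover_duration_h = sum(s_dur),
    distance_target_km = d_tgt,
    stringsAsFactors = FALSE)
  list(track = track, latent = latent)
}

#' Simulate a cohort of tracks with known truth
#'
#' Draws ancestry, individual and year random intercepts, assigns capture
#' states and migration years (a fixed fraction of birds contributes two
#' consecutive springs), and emits one track per bird-year. All randomness
#' flows from `truth$seed`, so a fixed seed reproduces the cohort exactly.
#'
#' @param truth a [simulation_truth()] object.
#' @param emit_fixes if `FALSE`, skip GPS emission and return latent
#'   phenology only (fast path for parameter-recovery studies); see
#'   [simulate_phenology()].
#' @return list of class `synthetic_cohort`: `tracks` (NULL when
#'   `emit_fixes = FALSE`), `ancestry`, `latent`, `truth`.
#' @export
simulate_cohort <- function(truth = simulation_truth(), emit_fixes = TRUE) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  n <- truth$n_individuals
  ids <- sprintf("bird%04d", seq_len(n))
  ancestry <- simulate_ancestry(n, truth$hybrid_prob, truth$max_gamefarm, ids)
  z <- standardize_predictor(ancestry$gamefarm_fraction)$x_std
  state <- ifelse(stats::runif(n) < truth$prop_AR, "AR", "TN")
  u <- stats::rnorm(n, 0, truth$sd_individual)
  v <- stats::setNames(stats::rnorm(length(truth$years), 0, truth$sd_year),
                       truth$years)
  n_rep <- round(truth$repeat_fraction * n)
  rep_ids <- if (n_rep > 0) sample.int(n, n_rep) else integer()
  yr_pool <- truth$years[-length(truth$years)]
  yr1 <- yr_pool[sample.int(length(yr_pool), n, replace = TRUE)]

  plan <- data.frame(i = c(seq_len(n), rep_ids),
                     year = c(yr1, yr1[rep_ids] + 1L))
  plan <- plan[order(plan$i, plan$year), ]

  tracks <- list()
  latents <- list()
  for (r in seq_len(nrow(plan))) {
    i <- plan$i[r]
    yr <- plan$year[r]
    sim <- simulate_track(ids[i], z[i], u[i], v[[as.character(yr)]],
                          state[i], yr, truth)
    latents[[r]] <- cbind(sim$latent,
                          gamefarm_fraction = ancestry$gamefarm_fraction[i])
    if (emit_fixes) tracks[[r]] <- sim$track
  }
  structure(list(tracks = if (emit_fixes) tracks else NULL,
                 ancestry = ancestry,
                 latent = do.call(rbind, latents),
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d individuals, %d tracks (seed %d)\n",
              x$truth$n_individuals, nrow(x$latent), x$truth$seed))
  invisible(x)
}

#' Simulate latent phenology records directly
#'
#' Fast path for parameter-recovery studies: draws the eight per-track
#' responses from the same linear/Poisson structure the track generator
#' uses, without emitting GPS fixes. Migration duration is arrival minus
#' departure; stopover total duration is a sum of 24-96 h dwells (zero when
#' the bird never stops); urban distance is log-normal with no ancestry
#' effect.
#'
#' @param truth a [simulation_truth()] object.
#' @return data frame shaped like the output of [segment_cohort()]'s
#'   `phenology` element, with attribute `"z"` holding the standardized
#'   ancestry used.
#' @export
simulate_phenology <- function(truth = simulation_truth()) {
  set.seed(truth$seed)
  n <- truth$n_individuals
  ids <- sprintf("bird%04d", seq_len(n))
  ancestry <- simulate_ancestry(n, truth$hybrid_prob, truth$max_gamefarm, ids)
  z <- standardize_predictor(ancestry$gamefarm_fraction)$x_std
  u <- stats::rnorm(n, 0, truth$sd_individual)
  v <- stats::setNames(stats::rnorm(length(truth$years), 0, truth$sd_year),
                       truth$years)
  n_rep <- round(truth$repeat_fraction * n)
  rep_ids <- if (n_rep > 0) sample.int(n, n_rep) else integer()
  yr_pool <- truth$years[-length(truth$years)]
  yr1 <- yr_pool[sample.int(length(yr_pool), n, replace = TRUE)]
  i <- c(seq_len(n), rep_ids)
  yr <- c(yr1, yr1[rep_ids] + 1L)

  m <- length(i)
  vy <- v[as.character(yr)]
  dep <- round(truth$baseline_departure_doy + truth$beta_departure * z[i] +
               u[i] + vy + stats::rnorm(m, 0, truth$sigma_departure))
  dep <- pmin(pmax(dep, 32), 151)
  arr <- round(truth$baseline_arrival_doy + truth$beta_arrival * z[i] +
               u[i] + vy + stats::rnorm(m, 0, truth$sigma_arrival))
  arr <- pmax(arr, dep + 1)
  lat <- pmax(truth$baseline_arrival_lat + truth$beta_latitude * z[i] +
              stats::rnorm(m, 0, truth$sigma_latitude), 43.2)
  dist <- pmax(truth$baseline_distance_km + truth$beta_distance * z[i] +
               stats::rnorm(m, 0, truth$sigma_distance), 300)
  k <- stats::rpois(m, truth$stopover_rate)
  sdur <- vapply(k, function(kk)
    if (kk == 0) 0 else
      sum(round(stats::runif(kk, truth$stopover_dur_h[1],
                             truth$stopover_dur_h[2]))),
    numeric(1))
  urb <- exp(stats::rnorm(m, log(25), 0.9))
  out <- data.frame(
    individual_id = ids[i], migration_year = yr,
    departure_doy = dep, arrival_doy = arr, arrival_lat = lat,
    migration_distance_km = dist,
    migration_duration_days = arr - dep,
    n_stopovers = k, stopover_duration_h = sdur,
    distance_to_urban_km = urb,
    gamefarm_fraction = ancestry$gamefarm_fraction[i],
    stringsAsFactors = FALSE)
  attr(out, "z") <- z[i]
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes `tracks.csv`, `ancestry.csv`, `latent.csv` and `truth.json` into a
#' directory. Byte-identical on repeated calls with the same cohort.
#'
#' @param cohort a [simulate_cohort()] result with emitted fixes.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"), !is.null(cohort$tracks))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(cohort$tracks, file.path(dir, "tracks.csv"))
  utils::write.csv(cohort$ancestry, file.path(dir, "ancestry.csv"),
                   row.names = FALSE)
  lat <- cohort$latent
  lat$arrival_time <- format(lat$arrival_time, "%Y-%m-%d %H:%M:%S",
                             tz = "UTC")
  lat$departure_time <- format(lat$departure_time, "%Y-%m-%d %H:%M:%S",
                               tz = "UTC")
  utils::write.csv(lat, file.path(dir, "latent.csv"), row.names = FALSE)
  tr <- cohort$truth
  class(tr) <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
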