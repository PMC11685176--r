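# Test fixtures and independent brute-force oracles.

# Build a track from hour offsets and coordinates.
make_track <- function(hours, lon, lat, state = "TN", year = 2022,
                       origin = sprintf("%d-02-01 00:00:00", year),
                       id = "bird") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  mig_track(id, state, year,
            data.frame(timestamp = t0 + hours * 3600, lon = lon, lat = lat))
}

# Random raw fix cloud: alternating dwell bouts (small displacements around
# an anchor) and jumps, over latitudes 35-48, with irregular fix intervals.
random_fix_track <- function(n_max = 200) {
  n <- sample(20:n_max, 1)
  dt <- stats::runif(n - 1, 0.5, 6)
  hours <- c(0, cumsum(dt))
  lon <- numeric(n)
  lat <- numeric(n)
  cur <- c(-90 + stats::runif(1, -2, 2), stats::runif(1, 35, 40))
  i <- 1
  while (i <= n) {
    bout <- min(sample(1:25, 1), n - i + 1)
    if (stats::runif(1) < 0.5) {
      # dwell around current anchor
      for (j in seq_len(bout)) {
        p <- migphen:::move_point(cur[1], cur[2], stats::runif(1, 0, 360),
                                  stats::runif(1, 0, 20))
        lon[i] <- p[1]; lat[i] <- p[2]; i <- i + 1
      }
    } else {
      # directed jumps
      for (j in seq_len(bout)) {
        cur <- migphen:::move_point(cur[1], cur[2],
                                    stats::rnorm(1, 0, 60),
                                    stats::runif(1, 30, 200))
        cur[2] <- min(max(cur[2], 34), 49)
        lon[i] <- cur[1]; lat[i] <- cur[2]; i <- i + 1
      }
    }
  }
  make_track(hours, lon, lat)
}

# Full pairwise great-circle distance matrix.
dist_matrix <- function(fx) {
  n <- nrow(fx)
  outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(fx$lon[i], fx$lat[i], fx$lon[j], fx$lat[j]))
}

# Residency oracle: test EVERY fix as an anchor independently against the
# latitude, record-length and dwell-radius conditions; earliest valid wins.
brute_residency <- function(track, departure_idx, rules) {
  fx <- track$fixes
  n <- nrow(fx)
  D <- dist_matrix(fx)
  tt <- as.numeric(fx$timestamp)
  valid <- integer()
  for (i in departure_idx:n) {
    if (fx$lat[i] <= rules$residency_lat_min) next
    if (tt[n] - tt[i] < rules$residency_min_days * 86400) next
    win <- which(tt >= tt[i] & tt <= tt[i] + rules$residency_min_days * 86400)
    if (all(D[i, win] <= rules$residency_radius_km)) valid <- c(valid, i)
  }
  if (length(valid)) min(valid) else NA_integer_
}

# Stopover oracle: precompute, for every fix, the maximal consecutive
# radius-bounded window anchored there, then select windows meeting the
# dwell minimum greedily by earliest anchor, skipping consumed fixes.
brute_stopovers <- function(track, departure_idx, residency_idx, rules) {
  fx <- track$fixes
  D <- dist_matrix(fx)
  tt <- as.numeric(fx$timestamp)
  lo <- departure_idx + 1L
  hi <- residency_idx - 1L
  if (hi < lo) return(data.frame(anchor = integer(), last = integer(),
                                 duration_hours = numeric()))
  win_end <- integer(hi)
  for (a in lo:hi) {
    m <- a
    while (m < hi && D[a, m + 1] <= rules$stopover_radius_km) m <- m + 1
    win_end[a] <- m
  }
  sel <- list()
  a <- lo
  while (a <= hi) {
    dur <- (tt[win_end[a]] - tt[a]) / 3600
    if (dur >= rules$stopover_min_hours) {
      sel[[length(sel) + 1L]] <- data.frame(anchor = a, last = win_end[a],
                                            duration_hours = dur)
      a <- win_end[a] + 1L
    } else a <- a + 1L
  }
  if (!length(sel)) return(data.frame(anchor = integer(), last = integer(),
                                      duration_hours = numeric()))
  do.call(rbind, sel)
}

# Classic (non-rank) Gelman-Rubin statistic, as an independent formula
# check applied to rank-normalized split draws.
psrf_formula <- function(mat) {
  n <- nrow(mat)
  W <- mean(apply(mat, 2, stats::var))
  B <- n * stats::var(colMeans(mat))
  sqrt(((n - 1) / n * W + B / n) / W)
}

write_geojson <- function(features, path) {
  jsonlite::write_json(features, path, auto_unbox = TRUE, digits = NA)
  path
}

# Rectangle polygon coordinates in GeoJSON nesting (list of rings of [lon,lat]).
gj_rect <- function(lon0, lon1, lat0, lat1) {
  list(list(list(lon0, lat0), list(lon1, lat0), list(lon1, lat1),
            list(lon0, lat1), list(lon0, lat0)))
}
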