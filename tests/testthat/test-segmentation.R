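test_that("step classification honors the printed class boundaries", {
  cls <- classify_step(c(0.1, 0.249999, 0.25, 5, 49.999, 50, 250))
  expect_equal(as.character(cls),
               c("wetland", "wetland", "local_regional", "local_regional",
                 "local_regional", "migration", "migration"))
  expect_error(classify_step(-1))
})

test_that("log-density breaks separate well-spaced movement modes", {
  set.seed(101)
  # three tight lognormal modes at 0.05, 5 and 200 km
  steps <- c(exp(rnorm(400, log(0.05), 0.3)),
             exp(rnorm(400, log(5), 0.3)),
             exp(rnorm(400, log(200), 0.3)))
  br <- log_step_density_breaks(steps)
  expect_length(br, 2)
  expect_gt(br[1], 0.05); expect_lt(br[1], 5)
  expect_gt(br[2], 5);    expect_lt(br[2], 200)
  # breaks sit near the analytic minima of the mixture density (log10 scale)
  grid <- seq(log10(0.005), log10(2000), length.out = 4000)
  dens <- function(g) {
    s <- 0.3 / log(10)  # lognormal sd expressed in log10 units
    (stats::dnorm(g, log10(0.05), s) + stats::dnorm(g, log10(5), s) +
       stats::dnorm(g, log10(200), s)) / 3
  }
  y <- dens(grid)
  i <- 2:(length(y) - 1)
  mins <- grid[i[y[i] < y[i - 1] & y[i] < y[i + 1]]]
  expect_length(mins, 2)
  expect_equal(log10(br), mins, tolerance = 0.2)

  # unimodal data has no interior minima
  expect_length(log_step_density_breaks(exp(rnorm(500, log(2), 0.3))), 0)
  # zeros are dropped with a warning before the log transform
  expect_warning(log_step_density_breaks(c(rep(0, 5),
                                           exp(rnorm(500, log(2), 0.3)))),
                 "zero step")
  expect_error(log_step_density_breaks(1:50), "at least 100")
})

test_that("departure is the first fix strictly above the state threshold", {
  # TN bird crossing 36.982 N on 1 Mar
  tr <- make_track(c(0, 24, 672, 696), rep(-89, 4),
                   c(36.5, 36.6, 37.1, 37.5),
                   origin = "2022-02-01 08:00:00")
  d <- detect_departure(tr)
  expect_equal(d$status, "ok")
  expect_equal(d$index, 3L)
  expect_equal(format(tr$fixes$timestamp[d$index], "%Y-%m-%d"), "2022-03-01")

  # crossing on 15 Jan and staying north is excluded by the season window
  tr <- make_track(c(0, 24, 48), rep(-89, 3), c(36.5, 37.1, 37.5),
                   origin = "2022-01-14 08:00:00")
  expect_equal(detect_departure(tr)$status, "excluded_by_season")

  # both season endpoints are legal departure dates
  tr <- make_track(c(0, 24), rep(-89, 2), c(36.5, 37.1),
                   origin = "2022-01-31 08:00:00")
  expect_equal(detect_departure(tr)$status, "ok")

  # a bird that never crosses has no departure
  tr <- make_track(c(0, 24, 48), rep(-89, 3), c(36.0, 36.5, 36.9))
  expect_equal(detect_departure(tr)$status, "no_departure")

  # sitting exactly on the threshold does not count ("exceeded" is strict)
  tr <- make_track(c(0, 24), rep(-89, 2), c(36.5, 36.982))
  expect_equal(detect_departure(tr)$status, "no_departure")

  # AR threshold is lower
  tr <- make_track(c(0, 24), rep(-91, 2), c(35.5, 36.0), state = "AR")
  expect_equal(detect_departure(tr)$index, 2L)
})

test_that("residency anchors at the earliest 10-day dwell above 43 N", {
  rules <- segmentation_rules()
  # 12 days of jitter within 5 km around a point at 45 N
  dwell_h <- seq(0, 12 * 24, by = 6)
  ang <- seq_along(dwell_h) * 2.4
  dlat <- 0.02 * sin(ang)
  dlon <- 0.02 * cos(ang)
  tr <- make_track(c(0, 2, 4, 6 + dwell_h),
                   c(-89, -89, -89, -89 + dlon),
                   c(36.5, 38, 41.5, 45 + dlat),
                   origin = "2022-03-01 08:00:00")
  r <- detect_residency(tr, 2L, rules)
  expect_equal(r$status, "ok")
  expect_equal(r$index, 4L)  # first fix of the dwell phase

  # 9-day dwell broken by a 100-km flight, then a 10-day dwell: the second
  # dwell wins, and agrees with the brute-force oracle
  d1 <- seq(0, 9 * 24, by = 6)
  d2 <- seq(0, 11 * 24, by = 6)
  tr <- make_track(c(0, 2, 4 + d1, 6 + max(d1) + 6 + d2),
                   c(-89, -89, rep(-89, length(d1)), rep(-89, length(d2))),
                   c(36.5, 41, rep(44, length(d1)), rep(44.9, length(d2))),
                   origin = "2022-03-01 08:00:00")
  r <- detect_residency(tr, 1L, rules)
  expect_equal(r$index, 2L + length(d1) + 1L)
  expect_equal(r$index, brute_residency(tr, 1L, rules))

  # a 12-day dwell at 42.5 N fails the latitude condition
  tr <- make_track(c(0, 2, 4 + seq(0, 12 * 24, by = 6)),
                   c(-89, -89, rep(-89, 49)),
                   c(36.5, 41, rep(42.5, 49)),
                   origin = "2022-03-01 08:00:00")
  expect_equal(detect_residency(tr, 1L, rules)$status, "no_residency")

  # record ending 8 days after the only candidate: no residency, no guess
  tr <- make_track(c(0, 2, 4 + seq(0, 8 * 24, by = 6)),
                   c(-89, -89, rep(-89, 33)),
                   c(36.5, 41, rep(45, 33)),
                   origin = "2022-03-01 08:00:00")
  expect_equal(detect_residency(tr, 1L, rules)$status, "no_residency")
})

test_that("stopovers are greedy earliest-anchor dwells of at least 24 h", {
  rules <- segmentation_rules()
  # one 30-h dwell within 10 km mid-migration
  dh <- seq(0, 30, by = 6)
  tr <- make_track(c(0, 2, 4 + dh, 8 + max(dh), 10 + max(dh),
                     12 + max(dh) + seq(0, 11 * 24, by = 6)),
                   c(-89, -89, rep(-89, length(dh)), -89, -89,
                     rep(-89, 45)),
                   c(36.5, 39, rep(40.5, length(dh)) +
                       0.04 * sin(seq_along(dh)), 42.2, 45,
                     rep(45.9, 45)),
                   origin = "2022-03-01 08:00:00")
  seg <- segment_track(tr)
  expect_equal(seg$status, "complete")
  st <- seg$stopovers
  expect_equal(nrow(st), 1)
  expect_equal(st$duration_hours, 30)

  # nonstop flight: no dwell reaches 24 h
  tr <- make_track(c(0, 2, 4, 6, 8, 10 + seq(0, 11 * 24, by = 6)),
                   rep(-89, 50),
                   c(36.5, 38, 39.5, 41, 43.5, rep(45.5, 45)),
                   origin = "2022-03-01 08:00:00")
  seg <- segment_track(tr)
  expect_equal(seg$status, "complete")
  expect_equal(nrow(seg$stopovers), 0)

  # two dwells (26 h and 40 h) separated by a 200-km flight; against oracle
  dA <- seq(0, 26, by = 2); dB <- seq(0, 40, by = 2)
  hrs <- c(0, 2, 4 + dA, 6 + max(dA) + dB,
           8 + max(dA) + max(dB) + seq(0, 11 * 24, by = 6))
  lats <- c(36.5, 38.5, rep(40, length(dA)), rep(41.8, length(dB)),
            rep(45.5, 45))
  tr <- make_track(hrs, rep(-89, length(hrs)), lats,
                   origin = "2022-03-01 08:00:00")
  seg <- segment_track(tr)
  st <- seg$stopovers
  expect_equal(nrow(st), 2)
  expect_equal(st$duration_hours, c(26, 40))
  orc <- brute_stopovers(tr, seg$departure_idx, seg$residency_idx,
                         segmentation_rules())
  expect_equal(st$anchor_idx, orc$anchor)
  expect_equal(st$duration_hours, orc$duration_hours)
})

test_that("phenology metrics follow the segmentation endpoints", {
  # two 111.195-km legs, residency 10.0 days after departure, no stopovers
  hrs <- c(0, 240, 356, 480 + seq(0, 11 * 24, by = 24))
  tr <- make_track(hrs, rep(-89, length(hrs)),
                   c(36.5, 44, 45, rep(46, 12)),
                   origin = "2022-02-19 08:00:00")
  seg <- segment_track(tr)
  expect_equal(seg$status, "complete")
  expect_equal(format(seg$departure_time, "%Y-%m-%d %H:%M"),
               "2022-03-01 08:00")
  ph <- compute_phenology(seg, gamefarm_fraction = 0.1)
  expect_equal(ph$migration_distance_km, 2 * pi / 180 * 6371.0088,
               tolerance = 1e-9)
  expect_equal(ph$migration_duration_days, 10.0)
  expect_equal(ph$n_stopovers, 0)
  expect_equal(ph$stopover_duration_h, 0)  # imputed zero, never stopped
  expect_equal(ph$arrival_lat, 46)
  expect_gte(ph$arrival_doy, ph$departure_doy)
  expect_true(is.na(ph$distance_to_urban_km))

  # incomplete segmentation refuses to produce a record
  tr2 <- make_track(c(0, 24), c(-89, -89), c(36.0, 36.5))
  expect_error(compute_phenology(segment_track(tr2), 0.1), "complete")
})

test_that("segmentation is idempotent and monotone in its rules", {
  set.seed(77)
  for (rep in 1:20) {
    tr <- random_fix_track(150)
    rules <- segmentation_rules()
    s1 <- segment_track(tr, rules)
    s2 <- segment_track(tr, rules)
    expect_identical(s1[names(s1) != "track"], s2[names(s2) != "track"])
    # shrinking the residency circle can never move the anchor earlier
    tight <- segmentation_rules(residency_radius_km = 10)
    r1 <- detect_residency(tr, 1L, rules)
    r2 <- detect_residency(tr, 1L, tight)
    if (!is.na(r1$index) && !is.na(r2$index))
      expect_gte(r2$index, r1$index)
    # raising the dwell minimum can never increase the stopover count
    n <- nrow(tr$fixes)
    st24 <- detect_stopovers(tr, 1L, n, rules)
    st48 <- detect_stopovers(tr, 1L, n,
                             segmentation_rules(stopover_min_hours = 48))
    expect_lte(nrow(st48), nrow(st24))
  }
})
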