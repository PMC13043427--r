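# Pause/flight segmentation, significant locations, home detection,
# occupancy profiles and entropy.

LAT0 <- 45.4384; LON0 <- 10.9916
north_of <- function(d_m) destination_point(LAT0, LON0, 0, d_m)

test_that("entropy matches hand values and input validation", {
  expect_identical(entropy_nats(1.0), 0)
  expect_identical(entropy_nats(numeric()), 0)
  expect_identical(entropy_nats(c(0, 0)), 0)
  expect_equal(entropy_nats(c(0.5, 0.5)), log(2))
  expect_equal(entropy_nats(0.6), -0.6 * log(0.6), tolerance = 1e-12)
  expect_equal(entropy_nats(0.6), 0.3065, tolerance = 1e-4)
  expect_error(entropy_nats(1.2), "<= 1")
  expect_error(entropy_nats(-0.1), ">= 0")
})

test_that("entropy is maximized at the uniform distribution over a simplex
          grid", {
  # enumerate 3-part compositions of 1 on a 0.05 grid
  g <- seq(0, 1, by = 0.05)
  best <- -Inf; best_p <- NULL
  for (a in g) for (b in g[g <= 1 - a + 1e-9]) {
    p <- c(a, b, max(0, 1 - a - b))
    h <- entropy_nats(p)
    if (h > best) { best <- h; best_p <- p }
  }
  expect_lt(max(abs(best_p - 1 / 3)), 0.051)  # within grid resolution
  expect_true(best <= log(3) + 1e-12)
  expect_gte(entropy_nats(rep(1 / 3, 3)), best)
})

test_that("pause segmentation finds stationary runs and ignores motion", {
  # all points at one coordinate for 2 h -> one 2 h pause
  dwell <- make_dwell(LAT0, LON0, 0, 7200)
  pp <- segment_pauses(dwell, 50, 300, point_span_s = 10)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$duration_s, 7200, tolerance = 0.01)
  expect_equal(haversine_m(pp$lat, pp$lon, LAT0, LON0), 0, tolerance = 1)

  # two 20-min clusters 500 m apart linked by a transit -> exactly 2 pauses
  b <- north_of(500)
  trk <- rbind(make_dwell(LAT0, LON0, 0, 1200),
               make_track(data.frame(lat = c(LAT0, b$lat),
                                     lon = c(LON0, b$lon)),
                          speed_ms = 1.4, dt_s = 10, t0 = 1200),
               make_dwell(b$lat, b$lon, 1560, 1200))
  pp2 <- segment_pauses(trk, 50, 300, point_span_s = 10)
  expect_equal(nrow(pp2), 2)
  expect_true(haversine_m(pp2$lat[2], pp2$lon[2], b$lat, b$lon) < 10)

  # continuous straight-line motion at walking speed -> no pauses
  far <- north_of(5000)
  mv <- make_track(data.frame(lat = c(LAT0, far$lat), lon = c(LON0, far$lon)),
                   speed_ms = 1.4, dt_s = 10)
  expect_equal(nrow(segment_pauses(mv, 50, 300, point_span_s = 10)), 0)

  # empty input -> empty output
  expect_equal(nrow(segment_pauses(mv[0])), 0)
})

test_that("pauses split at observation gaps so unobserved time is not
          counted", {
  d1 <- make_dwell(LAT0, LON0, 0, 3600)
  d2 <- make_dwell(LAT0, LON0, 3600 + 4 * 3600, 3600)  # 4 h outage between
  pp <- segment_pauses(rbind(d1, d2), 50, 300, gap_max_s = 900,
                       point_span_s = 10)
  expect_equal(nrow(pp), 2)
  expect_equal(sum(pp$duration_s), 7200, tolerance = 0.01)
})

test_that("flight extraction splits at directional changes", {
  b <- north_of(1000)
  # straight 1 km transit between two pauses -> one flight of ~1000 m
  trk <- rbind(make_dwell(LAT0, LON0, 0, 1200),
               make_track(data.frame(lat = c(LAT0, b$lat), lon = c(LON0, b$lon)),
                          speed_ms = 5, dt_s = 10, t0 = 1200),
               make_dwell(b$lat, b$lon, 1410, 1200))
  pp <- segment_pauses(trk, 50, 300, point_span_s = 10)
  fl <- extract_flights(trk, pp, 30)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$length_m, 1000, tolerance = 0.02)
  expect_equal(daily_distance_km(fl), 1, tolerance = 0.02)

  # right-angle path: north 500 m then east 500 m -> two ~500 m flights
  n5 <- north_of(500)
  e5 <- destination_point(n5$lat, n5$lon, 90, 500)
  trk2 <- make_track(data.frame(lat = c(LAT0, n5$lat, e5$lat),
                                lon = c(LON0, n5$lon, e5$lon)),
                     speed_ms = 5, dt_s = 10)
  fl2 <- extract_flights(trk2, segment_pauses(trk2, 50, 300), 30)
  expect_equal(nrow(fl2), 2)
  expect_equal(fl2$length_m, c(500, 500), tolerance = 0.03)

  # stationary day -> no flights
  dwell <- make_dwell(LAT0, LON0, 0, 7200)
  expect_equal(nrow(extract_flights(dwell, segment_pauses(dwell, 50, 300), 30)),
               0)
  expect_equal(daily_distance_km(NULL), 0)
  expect_equal(daily_distance_km(data.table::data.table(length_m = c(400, 600))), 1)
})

test_that("daily distance is invariant to translation and time shift", {
  set.seed(9)
  b <- north_of(800)
  trk <- rbind(make_dwell(LAT0, LON0, 0, 1200, noise_m = 3),
               make_track(data.frame(lat = c(LAT0, b$lat), lon = c(LON0, b$lon)),
                          speed_ms = 5, dt_s = 10, t0 = 1200, noise_m = 3),
               make_dwell(b$lat, b$lon, 1370, 1200, noise_m = 3))
  dist0 <- daily_distance_km(extract_flights(trk, segment_pauses(trk, 50, 300), 30))
  shifted <- data.table::copy(trk)[, `:=`(lat = lat + 0.3, lon = lon + 0.4,
                                          t = t + 86400)]
  dist1 <- daily_distance_km(
    extract_flights(shifted, segment_pauses(shifted, 50, 300), 30))
  expect_equal(dist1, dist0, tolerance = 0.02)
})

test_that("significant locations: qualification, separation, k selection", {
  set.seed(21)
  mk_pause <- function(lat, lon, dur, t0 = 0)
    data.table::data.table(start = t0, end = t0 + dur, lat = lat, lon = lon,
                           duration_s = dur)
  # all qualifying pauses within 10 m of one point -> a single location
  jit <- function(m) m / 111320
  p1 <- data.table::rbindlist(lapply(1:6, function(i)
    mk_pause(LAT0 + jit(runif(1, -5, 5)), LON0, 1200, i * 5000)))
  sl <- find_significant_locations(p1, 900, 50, seed = 1)
  expect_equal(nrow(sl), 1)

  # two pause groups 60 m apart -> two locations (60 > 50 m separation)
  b60 <- north_of(60)
  p2 <- rbind(p1, data.table::rbindlist(lapply(1:6, function(i)
    mk_pause(b60$lat + jit(runif(1, -3, 3)), b60$lon, 1500, 1e5 + i * 5000))))
  sl2 <- find_significant_locations(p2, 900, 50, seed = 1)
  expect_equal(nrow(sl2), 2)
  # brute-force cross-check with unweighted stats::kmeans at k = 2
  km <- kmeans(cbind(p2$lat, p2$lon), centers = 2, nstart = 10)
  expect_equal(sort(round(sl2$lat, 5)),
               unname(sort(round(km$centers[, 1], 5))), tolerance = 1e-4)

  # pauses of only 10 min never qualify
  p3 <- data.table::rbindlist(lapply(1:5, function(i)
    mk_pause(LAT0, LON0, 600, i * 5000)))
  expect_equal(nrow(find_significant_locations(p3, 900, 50, seed = 1)), 0)
  expect_equal(nrow(find_significant_locations(p3[0], 900, 50, seed = 1)), 0)

  # determinism under a fixed seed
  expect_identical(find_significant_locations(p2, 900, 50, seed = 4),
                   find_significant_locations(p2, 900, 50, seed = 4))
})

test_that("home is the location with the most 20:00-08:00 pause time", {
  b <- north_of(200)
  sig <- data.table::data.table(loc_id = 1:2, lat = c(LAT0, b$lat),
                                lon = c(LON0, b$lon),
                                total_pause_s = c(1, 1), is_home = FALSE)
  day0 <- as.numeric(as.POSIXct("2025-03-10 00:00:00", tz = "UTC"))
  mkp <- function(lat, lon, from_h, to_h, day) data.table::data.table(
    start = day0 + day * 86400 + from_h * 3600,
    end = day0 + day * 86400 + to_h * 3600,
    lat = lat, lon = lon, duration_s = (to_h - from_h) * 3600)
  # A holds all night pauses over 3 days, B all daytime pauses
  pauses <- data.table::rbindlist(c(
    lapply(0:2, function(d) mkp(LAT0, LON0, 21, 24, d)),
    lapply(0:2, function(d) mkp(b$lat, b$lon, 9, 18, d))))
  hm <- detect_home(sig, pauses, 50, tz = "UTC")
  expect_true(hm[loc_id == 1, is_home])
  # oracle: night minutes tally
  expect_equal(sum(pauses[lat == LAT0, duration_s]) / 60, 3 * 3 * 60)

  # equal night time, A has more daytime -> A wins the tie-break
  pauses2 <- data.table::rbindlist(list(
    mkp(LAT0, LON0, 21, 23, 0), mkp(b$lat, b$lon, 21, 23, 1),
    mkp(LAT0, LON0, 10, 16, 0)))
  hm2 <- detect_home(sig, pauses2, 50, tz = "UTC")
  expect_true(hm2[loc_id == 1, is_home])
  expect_error(detect_home(sig[0], pauses, 50), "no significant locations")
  # single location is trivially home
  expect_true(detect_home(sig[1], pauses, 50)$is_home)
})

test_that("night-window overlap handles intervals crossing midnight", {
  day0 <- as.numeric(as.POSIXct("2025-03-10 00:00:00", tz = "UTC"))
  # 22:00 to 07:00 next day: all 9 h are night
  expect_equal(mobiphen:::.night_overlap_s(day0 + 22 * 3600,
                                           day0 + 31 * 3600, "UTC"),
               9 * 3600)
  # 10:00 to 15:00: none
  expect_equal(mobiphen:::.night_overlap_s(day0 + 10 * 3600,
                                           day0 + 15 * 3600, "UTC"), 0)
  # 18:00 to 21:00: one hour
  expect_equal(mobiphen:::.night_overlap_s(day0 + 18 * 3600,
                                           day0 + 21 * 3600, "UTC"), 3600)
})

test_that("day profile normalizes occupancy over observed dwell", {
  b <- north_of(200)
  sig <- data.table::data.table(loc_id = 1:2, lat = c(LAT0, b$lat),
                                lon = c(LON0, b$lon),
                                total_pause_s = c(10, 5), is_home = c(TRUE, FALSE))
  pauses <- data.table::data.table(
    start = c(0, 50000), end = c(43200, 71600),
    lat = c(LAT0, b$lat), lon = c(LON0, b$lon),
    duration_s = c(12 * 3600, 6 * 3600))
  prof <- day_location_profile(pauses, sig, 50)
  expect_equal(prof$count, 2)
  expect_equal(unname(prof$p), c(2 / 3, 1 / 3))
  expect_equal(entropy_nats(prof$p), -2 / 3 * log(2 / 3) - 1 / 3 * log(1 / 3))
  expect_equal(daily_home_duration_h(pauses, sig[1], 50), 12)
  # no pauses -> empty profile
  expect_equal(day_location_profile(pauses[0], sig, 50)$count, 0)
  # whole day at one location
  prof1 <- day_location_profile(pauses[1], sig, 50)
  expect_equal(unname(prof1$p), 1)
  expect_equal(entropy_nats(prof1$p), 0)
})
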