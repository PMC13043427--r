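# The synthetic-cohort generator: day-plan rendering, ground-truth
# bookkeeping, seed determinism, null behavior, and calibration.

test_that("a degenerate stay-at-home day has zero mobility everywhere", {
  cfg <- tiny_cohort_config()
  plan <- day_plan(data.table::data.table(
    type = "stay", start = 0, end = 86400, lat = 45.5, lon = 11.0,
    lat2 = NA_real_, lon2 = NA_real_, mode = NA_character_, place_id = 0L))
  set.seed(1)
  sim <- simulate_patient_day(plan, cfg)
  expect_equal(sim$truth$distance_km, 0)
  expect_equal(sim$truth$home_hours, 24)
  expect_equal(sim$truth$sig_loc_entropy, 0)
  expect_equal(sim$truth$steps, 0)
  expect_equal(sim$truth$sig_loc_count, 1)
  # all GPS points within noise of home (5 sigma)
  d <- haversine_m(sim$gps$lat, sim$gps$lon, 45.5, 11.0)
  expect_true(all(d < 5 * cfg$gps_noise_sd_m))
  # GPS points exist only inside on-windows
  sod <- sim$gps$t %% (cfg$gps_on_s + cfg$gps_off_s)
  expect_true(all(sod < cfg$gps_on_s))
  # no walking -> every accel burst is gravity-only
  expect_equal(daily_steps(sim$accel, step_params(),
                           cfg$accel_on_s, cfg$accel_off_s), 0L)
})

test_that("a planned walk out and back yields exact path length and steps", {
  cfg <- tiny_cohort_config()
  b <- destination_point(45.5, 11.0, 90, 1000)
  walk_t <- 1800  # 30 min each way
  seg <- rbind(
    data.table::data.table(type = "stay", start = 0, end = 36000, lat = 45.5,
                           lon = 11.0, lat2 = NA_real_, lon2 = NA_real_,
                           mode = NA_character_, place_id = 0L),
    data.table::data.table(type = "move", start = 36000, end = 36000 + walk_t,
                           lat = 45.5, lon = 11.0, lat2 = b$lat, lon2 = b$lon,
                           mode = "walk", place_id = NA_integer_),
    data.table::data.table(type = "stay", start = 36000 + walk_t,
                           end = 36000 + walk_t + 7200, lat = b$lat,
                           lon = b$lon, lat2 = NA_real_, lon2 = NA_real_,
                           mode = NA_character_, place_id = 1L),
    data.table::data.table(type = "move", start = 36000 + walk_t + 7200,
                           end = 36000 + 2 * walk_t + 7200, lat = b$lat,
                           lon = b$lon, lat2 = 45.5, lon2 = 11.0,
                           mode = "walk", place_id = NA_integer_),
    data.table::data.table(type = "stay", start = 36000 + 2 * walk_t + 7200,
                           end = 86400, lat = 45.5, lon = 11.0,
                           lat2 = NA_real_, lon2 = NA_real_,
                           mode = NA_character_, place_id = 0L))
  set.seed(2)
  sim <- simulate_patient_day(day_plan(seg), cfg)
  # haversine oracle on the planned waypoints: 1 km out + 1 km back
  expect_equal(sim$truth$distance_km, 2.0, tolerance = 1e-6)
  expect_equal(sim$truth$steps, round(cfg$walk_cadence_hz * 3600))
  expect_equal(sim$truth$sig_loc_count, 2)
  # ground-truth entropy equals the entropy formula on the truth p vector
  expect_equal(sim$truth$sig_loc_entropy, entropy_nats(sim$truth$p))
})

test_that("overlapping schedule segments are rejected", {
  seg <- data.table::data.table(
    type = "stay", start = c(0, 1000), end = c(2000, 3000),
    lat = 45.5, lon = 11, lat2 = NA_real_, lon2 = NA_real_,
    mode = NA_character_, place_id = 0L)
  expect_error(day_plan(seg), "schedule error")
})

test_that("simulated cohorts are reproducible under a fixed seed", {
  cfg <- tiny_cohort_config(follow_up_days = 3)
  s1 <- simulate_cohort(cfg, seed = 5)
  s2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$proms, s2$proms)
  for (pid in names(s1$gps)) expect_identical(s1$gps[[pid]], s2$gps[[pid]])
  for (pid in names(s1$accel)) expect_identical(s1$accel[[pid]], s2$accel[[pid]])
})

test_that("total day-level missingness empties sensor streams and flags
          truth", {
  cfg <- tiny_cohort_config(day_missing_prob = 1, follow_up_days = 3)
  sim <- simulate_cohort(cfg, seed = 2)
  expect_true(all(sim$truth$missing))
  expect_true(all(vapply(sim$gps, nrow, integer(1)) == 0))
  expect_true(all(vapply(sim$accel, nrow, integer(1)) == 0))
})

test_that("truth distance and steps are zero exactly when the plan has no
          transit / walking", {
  cfg <- tiny_cohort_config(follow_up_days = 8)
  sim <- simulate_cohort(cfg, seed = 9)
  tr <- sim$truth[missing == FALSE]
  expect_true(all((tr$distance_km == 0) == (tr$n_visits == 0 & tr$loop_m == 0 &
                                              tr$walk_s == 0)))
  expect_true(all((tr$steps == 0) == (tr$walk_s == 0)))
  # occupancy bounds
  expect_true(all(tr$home_hours >= 0 & tr$home_hours <= 24))
  expect_true(all(tr$sig_loc_entropy >= 0))
})

test_that("flat trajectories produce no week-1 vs week-5 difference", {
  tg <- default_targets()
  for (arm in names(tg)) {
    tg[[arm]]$distance_km <- c(5, 5)
    tg[[arm]]$home_hours <- c(15, 15)
    tg[[arm]]$sig_loc_count <- c(1.5, 1.5)
    tg[[arm]]$sig_loc_entropy <- c(0.15, 0.15)
    tg[[arm]]$steps <- c(150, 150)
  }
  cfg <- cohort_config(n_patients = 200, n_anterior = 100,
                       follow_up_days = 35, targets = tg,
                       day_missing_prob = 0)
  tr <- simulate_truth(cfg, seed = 31)
  w1 <- tr[postop_day %in% 1:7]
  w5 <- tr[postop_day %in% 29:35]
  for (v in c("distance_km", "home_hours", "steps")) {
    p <- t.test(w1[[v]], w5[[v]])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("a zero PROM linkage coefficient kills the correlation", {
  pt <- default_prom_targets()
  pt$NDI$r <- 0
  pt$NDI$level <- "daily"
  # double-size cohort with full response: ~1800 paired days, so the
  # 1/sqrt(n) sampling bound of 0.1 sits at more than four standard errors
  cfg <- cohort_config(n_patients = 26, n_anterior = 12,
                       vas_response_prob = 1, prom_targets = pt)
  tr <- simulate_truth(cfg, seed = 13)
  tr[, rep := NULL]
  proms <- mobiphen:::.simulate_proms(cfg, tr)
  ndi <- proms[instrument == "NDI"]
  ndi[, postop_day := as.integer(date - cfg$surgery_date)]
  mm <- merge(ndi, tr, by = c("patient_id", "postop_day"))
  for (v in c("distance_km", "home_hours", "sig_loc_count",
              "sig_loc_entropy", "steps")) {
    expect_lt(abs(cor(mm$score, mm[[v]])), 0.1)
  }
})

test_that("ground-truth week summaries match a brute-force mean", {
  tr <- data.table::data.table(
    patient_id = rep(c("A", "B"), each = 35), postop_day = rep(1:35, 2),
    distance_km = 0, home_hours = 0, sig_loc_count = 0,
    sig_loc_entropy = 0, steps = 0, missing = FALSE)
  expect_equal(unname(ground_truth_summary(tr, 1)), rep(0, 5))

  set.seed(8)
  for (v in c("distance_km", "home_hours", "sig_loc_count",
              "sig_loc_entropy", "steps"))
    tr[[v]] <- runif(nrow(tr), 0, 10)
  gs <- ground_truth_summary(tr, 5)
  # spreadsheet-style recomputation
  sub <- tr[postop_day >= 29 & postop_day <= 35]
  expect_equal(gs[["distance_km"]], sum(sub$distance_km) / nrow(sub))
  expect_equal(gs[["steps"]], sum(sub$steps) / nrow(sub))
  # a week of identical rows returns the row
  tr2 <- data.table::copy(tr)[, distance_km := 7]
  expect_equal(ground_truth_summary(tr2, 2)[["distance_km"]], 7)
  expect_error(ground_truth_summary(tr, 6), "beyond follow-up")
  expect_error(suppressWarnings(ground_truth_summary(tr[missing == TRUE], 1)))
})

test_that("ground-truth week means track the reference table over seed
          replicates", {
  cfg <- cohort_config()
  ref <- reference_week_table()
  tr <- simulate_truth(cfg, seed = 101, n_rep = 20)
  hits <- matrix(0, nrow(ref), 2)
  for (r in 1:20) {
    g1 <- ground_truth_summary(tr[rep == r], 1)
    g5 <- ground_truth_summary(tr[rep == r], 5)
    # raw steps are the duty-cycled half of true steps
    g1[["steps"]] <- g1[["steps"]] / 2
    g5[["steps"]] <- g5[["steps"]] / 2
    hits[, 1] <- hits[, 1] + (g1[ref$variable] >= ref$lo1 &
                                g1[ref$variable] <= ref$hi1)
    hits[, 2] <- hits[, 2] + (g5[ref$variable] >= ref$lo5 &
                                g5[ref$variable] <= ref$hi5)
  }
  expect_true(all(hits / 20 >= 0.8))
})
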