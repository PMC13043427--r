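# Shared fixtures: hand-built GPS tracks, small cohort configurations, and
# a lazily computed full default-cohort study run reused across the
# acceptance-level tests.

# Build a continuous GPS track through waypoints at constant speed.
# waypoints: data.frame(lat, lon); returns data.table(t, lat, lon).
make_track <- function(waypoints, speed_ms = 1.4, dt_s = 1, t0 = 0,
                       noise_m = 0) {
  pts <- list()
  t_cur <- t0
  for (i in seq_len(nrow(waypoints) - 1)) {
    d <- haversine_m(waypoints$lat[i], waypoints$lon[i],
                     waypoints$lat[i + 1], waypoints$lon[i + 1])
    dur <- d / speed_ms
    tt <- seq(0, dur, by = dt_s)
    fr <- tt / dur
    pts[[i]] <- data.table::data.table(
      t = t_cur + tt,
      lat = waypoints$lat[i] + fr * (waypoints$lat[i + 1] - waypoints$lat[i]),
      lon = waypoints$lon[i] + fr * (waypoints$lon[i + 1] - waypoints$lon[i]))
    t_cur <- t_cur + dur
  }
  out <- data.table::rbindlist(pts)
  out <- out[!duplicated(t)]
  if (noise_m > 0) {
    out[, lat := lat + rnorm(.N, 0, noise_m / 111320)]
    out[, lon := lon + rnorm(.N, 0, noise_m / (111320 * cos(lat[1] * pi / 180)))]
  }
  out
}

# A stationary dwell at one coordinate.
make_dwell <- function(lat, lon, t0, dur_s, dt_s = 10, noise_m = 0) {
  tt <- seq(t0, t0 + dur_s - dt_s, by = dt_s)
  out <- data.table::data.table(t = tt, lat = lat, lon = lon)
  if (noise_m > 0) {
    out[, lat := lat + rnorm(.N, 0, noise_m / 111320)]
    out[, lon := lon + rnorm(.N, 0, noise_m / (111320 * cos(lat * pi / 180)))]
  }
  out
}

# A walking-burst magnitude signal: baseline 1 g plus a cadence sinusoid.
make_walk_burst <- function(dur_s = 10, fs = 10, cadence_hz = 2, amp_g = 0.3,
                            noise_g = 0) {
  tt <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  1 + amp_g * sin(2 * pi * cadence_hz * tt) + rnorm(length(tt), 0, noise_g)
}

# Small, cheap cohort configuration for module tests.
tiny_cohort_config <- function(n_patients = 3, n_anterior = 1,
                               follow_up_days = 10, day_missing_prob = 0,
                               ...) {
  cohort_config(n_patients = n_patients, n_anterior = n_anterior,
                follow_up_days = follow_up_days,
                day_missing_prob = day_missing_prob, ...)
}

# Lazily computed full default study run (seed 1), shared by the
# acceptance-level tests so the expensive pipeline executes once.
.study_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.study_cache$run)) .study_cache$run <- run_study(seed = 1L)
  .study_cache$run
}

# Printed week-1 / week-5 reference means and 95% CIs the calibrated
# simulation is checked against.
reference_week_table <- function() {
  data.table::data.table(
    variable = c("distance_km", "home_hours", "sig_loc_count",
                 "sig_loc_entropy", "steps"),
    mean1 = c(3.04, 14.63, 1.33, 0.10, 108.83),
    lo1 = c(2.34, 13.62, 1.26, 0.08, 90.70),
    hi1 = c(3.73, 15.64, 1.40, 0.12, 126.96),
    mean5 = c(13.89, 14.05, 2.44, 0.26, 250),
    lo5 = c(12.17, 13.13, 2.28, 0.23, 222.88),
    hi5 = c(15.60, 14.98, 2.61, 0.29, 277.13))
}
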