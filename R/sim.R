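# Synthetic post-surgical cohort generator. Ground truth comes first: daily
# schedules (stays at significant places, vehicle errands, walking bouts,
# sensor outages) are drawn from the calibrated parameter curves, then raw
# duty-cycled GPS and accelerometer streams are rendered from the schedule.
# Ground-truth rows record exact haversine path lengths, observable stay
# occupancies and steps = cadence x walking seconds, independently of the
# extraction code.

.TRUTH_VARS <- c("distance_km", "home_hours", "sig_loc_count",
                 "sig_loc_entropy", "steps")

# margin kept at each end of a home interval when carving sensor outages,
# so the flanking home dwell still registers as a qualifying pause
.OUTAGE_MARGIN_S <- 1260

# ---------------------------------------------------------------------------
# cohort-level truth draw

.draw_patients <- function(cfg) {
  n <- cfg$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  arm <- c(rep("anterior", cfg$n_anterior),
           rep("posterior", n - cfg$n_anterior))
  age <- round(ifelse(arm == "anterior", rnorm(n, 50, 8), rnorm(n, 67, 6)))
  age <- pmin(pmax(age, 25), 88)
  sex <- rep("M", n)
  n_f <- max(1L, round(n * 3 / 13))
  f_idx <- c(head(which(arm == "anterior"), ceiling(n_f * 2 / 3)),
             head(which(arm == "posterior"), n_f - ceiling(n_f * 2 / 3)))
  sex[f_idx] <- "F"
  levels_v <- sample(rep(1:4, times = pmax(1, round(c(4, 6, 2, 1) / 13 * n)))[seq_len(n)])
  instr <- sample(rep(c(TRUE, FALSE), times = c(ceiling(9 / 13 * n),
                                                n - ceiling(9 / 13 * n))))
  home_lat <- 45.40 + 0.05 * seq_len(n)
  home_lon <- 10.90 + 0.002 * seq_len(n)
  data.table(patient_id = ids, approach = arm, age = age, sex = sex,
             levels = levels_v, instrumentation = instr,
             surgery_date = cfg$surgery_date, timezone = cfg$timezone,
             home_lat = home_lat, home_lon = home_lon)
}

.draw_places <- function(cfg, patients) {
  out <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    k <- cfg$n_places
    brg <- (seq_len(k) - 1) * 360 / k + runif(k, -20, 20)
    dst <- runif(k, cfg$place_dist_range_m[1], cfg$place_dist_range_m[2])
    ll <- destination_point(patients$home_lat[i], patients$home_lon[i], brg, dst)
    out[[i]] <- data.table(patient_id = patients$patient_id[i],
                           place_id = seq_len(k), lat = ll$lat, lon = ll$lon,
                           dist_m = dst)
  }
  rbindlist(out)
}

# Draw per patient-day schedule parameters and schedule-implied truth.
# Consumes the current RNG stream; deterministic given the caller's seed.
.draw_cohort_truth <- function(cfg) {
  patients <- .draw_patients(cfg)
  places <- .draw_places(cfg, patients)
  n <- nrow(patients)
  eff <- data.table(
    patient_id = patients$patient_id,
    arm = patients$approach,
    e_dist = exp(rnorm(n, 0, cfg$sd_log_distance_patient) -
                   cfg$sd_log_distance_patient^2 / 2),
    e_walk = exp(rnorm(n, 0, cfg$sd_log_walk_patient) -
                   cfg$sd_log_walk_patient^2 / 2),
    e_home = rnorm(n, 0, cfg$sd_home_patient_h)
  )
  place_dist <- split(places$dist_m, places$patient_id)
  day_rows <- vector("list", cfg$follow_up_days)
  visit_rows <- vector("list", cfg$follow_up_days)
  for (d in seq_len(cfg$follow_up_days)) {
    n_visits <- integer(n); dwell_h <- numeric(n)
    for (arm in c("anterior", "posterior")) {
      idx <- which(eff$arm == arm)
      na <- length(idx)
      cv <- .curve_values(cfg, arm, d)
      # stratified uniforms keep the cohort-day visit-count distribution tight
      u <- (sample(na) - runif(na)) / na
      n_visits[idx] <- stats::qbinom(u, cfg$max_visits, cv$visit_p)
      z <- rnorm(na)
      dwell_h[idx] <- pmax(cfg$min_dwell_h,
                           cv$dwell_h * exp(cfg$sd_log_dwell * z -
                                              cfg$sd_log_dwell^2 / 2))
    }
    cva <- lapply(c(anterior = "anterior", posterior = "posterior"),
                  function(a) .curve_values(cfg, a, d))
    pick <- function(field) {
      v <- numeric(n)
      for (a in c("anterior", "posterior"))
        v[eff$arm == a] <- cva[[a]][[field]]
      v
    }
    D_km <- pick("distance_km") * eff$e_dist *
      exp(rnorm(n, 0, cfg$sd_log_distance) - cfg$sd_log_distance^2 / 2)
    H_h <- pick("home_h") + eff$e_home + rnorm(n, 0, cfg$sd_home_h)
    walk_s <- pick("walk_s") * eff$e_walk *
      exp(rnorm(n, 0, cfg$sd_log_walk) - cfg$sd_log_walk^2 / 2)
    missing <- runif(n) < cfg$day_missing_prob
    visit_place <- vector("list", n)
    G_m <- numeric(n)
    for (i in seq_len(n)) {
      if (n_visits[i] > 0) {
        pl <- sample(cfg$n_places, n_visits[i])
        visit_place[[i]] <- pl
        G_m[i] <- 2 * sum(place_dist[[patients$patient_id[i]]][pl])
      }
    }
    walk_m <- walk_s * cfg$walk_speed_ms
    loop_m <- pmax(0, D_km * 1000 - G_m - walk_m)
    transit_h <- (G_m + loop_m) / cfg$vehicle_speed_ms / 3600 + walk_s / 3600
    stops_h <- (loop_m > 0) * cfg$loop_stop_s / 3600
    busy_h <- n_visits * dwell_h + transit_h + stops_h
    H_h <- pmin(pmax(H_h, 4), 24 - busy_h - 0.25)
    A_h <- n_visits * dwell_h
    s <- ifelse(n_visits > 0, A_h / (A_h + H_h), 0)
    ent <- .binary_entropy(s) + s * log(pmax(n_visits, 1))
    day_rows[[d]] <- data.table(
      patient_id = patients$patient_id, arm = eff$arm, postop_day = d,
      n_visits = n_visits, dwell_h = dwell_h, walk_s = walk_s,
      loop_m = loop_m, visit_m = G_m, missing = missing,
      distance_km = (G_m + loop_m + walk_m) / 1000,
      home_hours = H_h,
      sig_loc_count = 1L + n_visits,
      sig_loc_entropy = ent,
      steps = round(cfg$walk_cadence_hz * walk_s)
    )
    vp <- which(n_visits > 0)
    if (length(vp))
      visit_rows[[d]] <- data.table(
        patient_id = rep(patients$patient_id[vp], n_visits[vp]),
        postop_day = d,
        place_id = unlist(visit_place[vp]))
  }
  list(patients = patients, places = places,
       days = rbindlist(day_rows),
       visits = rbindlist(Filter(Negate(is.null), visit_rows)))
}

#' Simulate ground truth only (no sensor rendering)
#'
#' Fast path producing the schedule-implied true daily mobility values for
#' one or more cohort replicates; used for calibration checks and
#' large-replicate properties.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @param n_rep number of independent cohort replicates.
#' @return a `data.table` with `rep`, `patient_id`, `arm`, `postop_day`,
#'   the five true mobility variables and a `missing` flag.
#' @export
simulate_truth <- function(cfg, seed = 1L, n_rep = 1L) {
  .with_seed(seed, {
    out <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      dr <- .draw_cohort_truth(cfg)
      out[[r]] <- cbind(rep = r, dr$days)
    }
    rbindlist(out)
  })
}

#' Pooled ground-truth week means
#'
#' Arithmetic mean of each true mobility variable over the 7 patient-days
#' of a post-operative week, pooled across patients (missing-flagged days
#' excluded).
#'
#' @param truth a ground-truth table ([simulate_truth()] or the `truth`
#'   element of [simulate_cohort()]).
#' @param week post-operative week index (week 1 = days 1-7).
#' @return named numeric vector of per-variable means.
#' @export
ground_truth_summary <- function(truth, week) {
  truth <- as.data.table(truth)
  days <- .WEEK_DAYS(week)
  if (max(days) > max(truth$postop_day))
    stop("ground_truth_summary: week ", week, " extends beyond follow-up")
  sub <- truth[postop_day %in% days & missing == FALSE]
  if (nrow(sub) == 0) stop("ground_truth_summary: week ", week, " is empty")
  vapply(.TRUTH_VARS, function(v) mean(sub[[v]]), numeric(1))
}

# ---------------------------------------------------------------------------
# day plans

#' Construct and validate a day plan
#'
#' A day plan is the schedule a simulated day is rendered from: an ordered
#' set of segments (`stay` at a place, or `move` between coordinates at a
#' given mode/speed) over seconds 0-86400, plus sensor outage windows.
#'
#' @param segments `data.table` with columns `type` ("stay"/"move"),
#'   `start`, `end` (seconds of day), `lat`, `lon` (stay position / move
#'   origin), `lat2`, `lon2` (move destination, `NA` for stays), `mode`
#'   ("walk"/"vehicle" for moves), `place_id` (0 = home, positive =
#'   candidate significant place, `NA` = non-significant stop).
#' @param outages optional `data.table` with `start`, `end` sensor-off
#'   windows (seconds of day).
#' @return list of class `mobiphen_day_plan`.
#' @export
day_plan <- function(segments, outages = NULL) {
  segments <- as.data.table(segments)
  setorder(segments, start)
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)] - 1e-9))
    stop("schedule error: overlapping stays/moves in day plan")
  if (any(segments$end <= segments$start))
    stop("schedule error: segment with non-positive duration")
  if (is.null(outages))
    outages <- data.table(start = numeric(), end = numeric())
  structure(list(segments = segments, outages = as.data.table(outages)),
            class = "mobiphen_day_plan")
}

.stay_row <- function(start, end, lat, lon, place_id) {
  data.table(type = "stay", start = start, end = end, lat = lat, lon = lon,
             lat2 = NA_real_, lon2 = NA_real_, mode = NA_character_,
             place_id = place_id)
}

.move_row <- function(start, end, lat, lon, lat2, lon2, mode) {
  data.table(type = "move", start = start, end = end, lat = lat, lon = lon,
             lat2 = lat2, lon2 = lon2, mode = mode, place_id = NA_integer_)
}

# Build the rendered schedule for one patient-day from its drawn
# parameters. Consumes RNG (jitters, bearings, outage placement).
.build_day_plan <- function(day, visits, places, home, cfg) {
  segs <- list()
  acts <- list()
  if (day$n_visits >= 1) {
    pls <- places[place_id %in% visits$place_id]
    for (j in seq_len(nrow(pls))) {
      tt <- pls$dist_m[j] / cfg$vehicle_speed_ms
      acts[[length(acts) + 1]] <- list(
        kind = "visit", dur = 2 * tt + day$dwell_h * 3600,
        make = local({
          p <- pls[j]; tt <- tt; dwell <- day$dwell_h * 3600
          function(t0) rbind(
            .move_row(t0, t0 + tt, home$lat, home$lon, p$lat, p$lon, "vehicle"),
            .stay_row(t0 + tt, t0 + tt + dwell, p$lat, p$lon, p$place_id),
            .move_row(t0 + tt + dwell, t0 + 2 * tt + dwell,
                      p$lat, p$lon, home$lat, home$lon, "vehicle"))
        }))
      if (j == 1 && day$walk_s > 0) acts[[length(acts) + 1]] <- .walk_act(day, home, cfg)
      if (j == 1 && day$loop_m > 0) acts[[length(acts) + 1]] <- .loop_act(day, home, cfg)
    }
  } else {
    if (day$walk_s > 0) acts[[length(acts) + 1]] <- .walk_act(day, home, cfg)
    if (day$loop_m > 0) acts[[length(acts) + 1]] <- .loop_act(day, home, cfg)
  }
  t0 <- (8 + runif(1, -0.5, 0.5)) * 3600
  gaps <- runif(length(acts), 0.5, 1.1) * 3600
  total_act <- sum(vapply(acts, `[[`, numeric(1), "dur"))
  if (t0 + total_act + sum(gaps) > 23 * 3600)
    gaps <- gaps * max(0, (23 * 3600 - t0 - total_act)) / max(sum(gaps), 1)
  cursor <- t0
  home_breaks <- numeric()
  for (i in seq_along(acts)) {
    segs[[length(segs) + 1]] <- acts[[i]]$make(cursor)
    home_breaks <- c(home_breaks, cursor, cursor + acts[[i]]$dur)
    cursor <- cursor + acts[[i]]$dur + gaps[i]
  }
  act_segs <- if (length(segs)) rbindlist(segs) else NULL
  # home stays fill the complement
  bounds <- matrix(c(0, home_breaks, 86400), ncol = 2, byrow = TRUE)
  home_segs <- rbindlist(lapply(seq_len(nrow(bounds)), function(i) {
    if (bounds[i, 2] - bounds[i, 1] < 1) return(NULL)
    .stay_row(bounds[i, 1], bounds[i, 2], home$lat, home$lon, 0L)
  }))
  segments <- rbind(home_segs, act_segs)
  setorder(segments, start)
  # sensor outages inside home intervals: total observed home == target
  home_int <- segments[type == "stay" & place_id == 0L, .(start, end)]
  O <- sum(home_int$end - home_int$start) - day$home_hours * 3600
  outages <- list()
  if (O > 60) {
    ord <- order(-(home_int$end - home_int$start))
    ord <- c(1L, setdiff(ord, 1L))  # night interval first
    for (i in ord) {
      cap <- home_int$end[i] - home_int$start[i] - 2 * .OUTAGE_MARGIN_S
      if (cap <= 0) next
      take <- min(O, cap)
      outages[[length(outages) + 1]] <-
        data.table(start = home_int$start[i] + .OUTAGE_MARGIN_S,
                   end = home_int$start[i] + .OUTAGE_MARGIN_S + take)
      O <- O - take
      if (O <= 0) break
    }
  }
  day_plan(segments, if (length(outages)) rbindlist(outages) else NULL)
}

.walk_act <- function(day, home, cfg) {
  half_m <- day$walk_s * cfg$walk_speed_ms / 2
  brg <- runif(1, 0, 360)
  w <- destination_point(home$lat, home$lon, brg, half_m)
  dur <- day$walk_s
  list(kind = "walk", dur = dur, make = function(t0) rbind(
    .move_row(t0, t0 + dur / 2, home$lat, home$lon, w$lat, w$lon, "walk"),
    .move_row(t0 + dur / 2, t0 + dur, w$lat, w$lon, home$lat, home$lon, "walk")))
}

.loop_act <- function(day, home, cfg) {
  half_m <- day$loop_m / 2
  brg <- runif(1, 0, 360)
  w <- destination_point(home$lat, home$lon, brg, half_m)
  tt <- half_m / cfg$vehicle_speed_ms
  stop_s <- cfg$loop_stop_s
  list(kind = "loop", dur = 2 * tt + stop_s, make = function(t0) rbind(
    .move_row(t0, t0 + tt, home$lat, home$lon, w$lat, w$lon, "vehicle"),
    .stay_row(t0 + tt, t0 + tt + stop_s, w$lat, w$lon, NA_integer_),
    .move_row(t0 + tt + stop_s, t0 + 2 * tt + stop_s,
              w$lat, w$lon, home$lat, home$lon, "vehicle")))
}

# ---------------------------------------------------------------------------
# sensor rendering

.overlap_s <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

.in_windows <- function(t, win) {
  if (is.null(win) || nrow(win) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(win))) out <- out | (t >= win$start[i] & t < win$end[i])
  out
}

# truth row implied by a plan: exact path length, observable occupancies,
# steps = cadence x walking seconds
.plan_truth <- function(plan, cfg) {
  seg <- plan$segments
  mv <- seg[type == "move"]
  dist_m <- if (nrow(mv)) sum(haversine_m(mv$lat, mv$lon, mv$lat2, mv$lon2)) else 0
  walk_s <- if (nrow(mv)) sum((mv$end - mv$start)[mv$mode == "walk"]) else 0
  st <- seg[type == "stay" & !is.na(place_id)]
  occ <- numeric()
  if (nrow(st)) {
    obs <- st$end - st$start
    if (nrow(plan$outages)) {
      for (i in seq_len(nrow(st)))
        obs[i] <- obs[i] - sum(.overlap_s(st$start[i], st$end[i],
                                          plan$outages$start, plan$outages$end))
    }
    occ <- tapply(obs, st$place_id, sum)
    occ <- occ[occ > 0]
  }
  p <- if (length(occ)) as.numeric(occ) / sum(occ) else numeric()
  list(
    distance_km = dist_m / 1000,
    home_hours = if ("0" %in% names(occ)) unname(occ["0"]) / 3600 else 0,
    sig_loc_count = length(occ),
    # entropy written out directly so the ground truth shares no code with
    # the extractor's entropy_nats()
    sig_loc_entropy = if (length(p)) -sum(p[p > 0] * log(p[p > 0])) else 0,
    steps = round(cfg$walk_cadence_hz * walk_s),
    walking_s = walk_s,
    p = p
  )
}

#' Render one simulated patient-day from a day plan
#'
#' Produces duty-cycled raw GPS points (stay points are the place plus
#' isotropic Gaussian noise; transit points interpolate at constant speed),
#' accelerometer bursts (a cadence-frequency oscillation during walking
#' windows, gravity plus noise otherwise) and the plan-implied ground-truth
#' row. Sensor outage windows silence both streams.
#'
#' @param plan a [day_plan()].
#' @param cfg a [cohort_config()].
#' @param day_epoch UTC epoch seconds of the day's local midnight; output
#'   timestamps are `day_epoch` + seconds of day.
#' @return list with `gps`, `accel` (data.tables) and `truth` (list).
#' @export
simulate_patient_day <- function(plan, cfg, day_epoch = 0) {
  stopifnot(inherits(plan, "mobiphen_day_plan"))
  seg <- plan$segments
  truth <- .plan_truth(plan, cfg)

  gps_period <- cfg$gps_on_s + cfg$gps_off_s
  w_starts <- seq(0, 86400 - 1, by = gps_period)
  off <- seq(0, cfg$gps_on_s - 1 / cfg$gps_hz, by = 1 / cfg$gps_hz)
  t <- rep(w_starts, each = length(off)) + off
  t <- t[!.in_windows(t, plan$outages)]
  idx <- findInterval(t, seg$start)
  ok <- idx >= 1 & t < seg$end[pmax(idx, 1)]
  t <- t[ok]; idx <- idx[ok]
  lat <- seg$lat[idx]; lon <- seg$lon[idx]
  is_mv <- seg$type[idx] == "move"
  if (any(is_mv)) {
    fr <- (t[is_mv] - seg$start[idx[is_mv]]) /
      (seg$end[idx[is_mv]] - seg$start[idx[is_mv]])
    lat[is_mv] <- lat[is_mv] + fr * (seg$lat2[idx[is_mv]] - lat[is_mv])
    lon[is_mv] <- lon[is_mv] + fr * (seg$lon2[idx[is_mv]] - lon[is_mv])
  }
  sd_lat <- cfg$gps_noise_sd_m / 111320
  sd_lon <- cfg$gps_noise_sd_m / (111320 * cos(.deg2rad(mean(seg$lat))))
  gps <- data.table(t = day_epoch + t,
                    lat = lat + rnorm(length(t), 0, sd_lat),
                    lon = lon + rnorm(length(t), 0, sd_lon),
                    accuracy = 10)

  acc_period <- cfg$accel_on_s + cfg$accel_off_s
  b_starts <- seq(0, 86400 - 1, by = acc_period)
  if (nrow(plan$outages)) {
    drop <- rep(FALSE, length(b_starts))
    for (i in seq_len(nrow(plan$outages)))
      drop <- drop | (b_starts < plan$outages$end[i] &
                        b_starts + cfg$accel_on_s > plan$outages$start[i])
    b_starts <- b_starts[!drop]
  }
  walk_win <- seg[type == "move" & mode == "walk", .(start, end)]
  active <- rep(FALSE, length(b_starts))
  if (nrow(walk_win)) {
    for (i in seq_len(nrow(walk_win)))
      active <- active | (b_starts < walk_win$end[i] &
                            b_starts + cfg$accel_on_s > walk_win$start[i])
  }
  keep <- active | (runif(length(b_starts)) < cfg$accel_idle_keep_frac)
  b_starts <- b_starts[keep]
  a_off <- seq(0, cfg$accel_on_s - 1 / cfg$accel_hz, by = 1 / cfg$accel_hz)
  ta <- rep(b_starts, each = length(a_off)) + a_off
  na <- length(ta)
  zsig <- rep(1, na)
  if (nrow(walk_win)) {
    wm <- .in_windows(ta, walk_win)
    zsig[wm] <- 1 + cfg$step_amp_g *
      sin(2 * pi * cfg$walk_cadence_hz * ta[wm])
  }
  accel <- data.table(t = day_epoch + ta,
                      x = rnorm(na, 0, cfg$accel_noise_sd_g),
                      y = rnorm(na, 0, cfg$accel_noise_sd_g),
                      z = zsig + rnorm(na, 0, cfg$accel_noise_sd_g))
  list(gps = gps, accel = accel, truth = truth)
}

# ---------------------------------------------------------------------------
# full cohort

#' Simulate a full calibrated cohort
#'
#' Draws daily schedules from the calibrated parameter curves, renders raw
#' duty-cycled sensor streams per patient-day, and generates PROMs linked
#' to the true mobility values. Deterministic under a fixed seed.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @return a `mobiphen_cohort` list (`patients`, `proms`, `gps`, `accel`)
#'   with a `truth` ground-truth `data.table` attached.
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  .with_seed(seed, {
    dr <- .draw_cohort_truth(cfg)
    patients <- dr$patients
    day0 <- as.numeric(as.POSIXct(paste(cfg$surgery_date, "00:00:00"),
                                  tz = cfg$timezone))
    gps <- list(); accel <- list()
    truth <- copy(dr$days)
    for (col in c("distance_km", "home_hours", "sig_loc_entropy"))
      truth[, (col) := as.numeric(get(col))]
    for (i in seq_len(nrow(patients))) {
      pid <- patients$patient_id[i]
      home <- list(lat = patients$home_lat[i], lon = patients$home_lon[i])
      pl <- dr$places[patient_id == pid]
      pdays <- dr$days[patient_id == pid]
      g_acc <- vector("list", nrow(pdays)); a_acc <- vector("list", nrow(pdays))
      for (j in seq_len(nrow(pdays))) {
        day <- pdays[j]
        if (day$missing) next
        vis <- dr$visits[patient_id == pid & postop_day == day$postop_day]
        plan <- .build_day_plan(day, vis, pl, home, cfg)
        sim <- simulate_patient_day(plan, cfg,
                                    day_epoch = day0 + day$postop_day * 86400)
        g_acc[[j]] <- sim$gps; a_acc[[j]] <- sim$accel
        for (v in .TRUTH_VARS)
          truth[patient_id == pid & postop_day == day$postop_day,
                (v) := sim$truth[[v]]]
      }
      gps[[pid]] <- rbindlist(Filter(Negate(is.null), g_acc))
      accel[[pid]] <- rbindlist(Filter(Negate(is.null), a_acc))
      if (nrow(gps[[pid]]) == 0)
        gps[[pid]] <- data.table(t = numeric(), lat = numeric(),
                                 lon = numeric(), accuracy = numeric())
      if (nrow(accel[[pid]]) == 0)
        accel[[pid]] <- data.table(t = numeric(), x = numeric(),
                                   y = numeric(), z = numeric())
    }
    proms <- .simulate_proms(cfg, truth)
    meta <- patients[, .(patient_id, age, sex, approach, levels,
                         instrumentation, surgery_date, timezone)]
    structure(list(patients = meta, proms = proms, gps = gps, accel = accel,
                   truth = truth),
              class = "mobiphen_cohort")
  })
}

# PROMs linear in log true mobility plus calibrated noise, truncated and
# rounded to the instrument's native scale.
.simulate_proms <- function(cfg, truth) {
  rows <- list()
  for (ins in names(cfg$prom_links)) {
    lk <- cfg$prom_links[[ins]]
    if (lk$level == "daily") {
      resp <- runif(nrow(truth)) < cfg$vas_response_prob
      sub <- truth[resp]
      x <- sub[[lk$variable]]
      y0 <- lk$c0 + lk$c1 * log(pmax(x, 1e-6))
      if (lk$c1 == 0) {
        eps <- rnorm(nrow(sub), 0, lk$sigma)
      } else {
        e1 <- .orth_noise(x, nrow(sub), 1)
        eps <- .pin_sigma(x, y0, e1, lk) * e1
      }
      sc <- pmin(pmax(round(y0 + eps), lk$range[1]), lk$range[2])
      rows[[ins]] <- data.table(
        patient_id = sub$patient_id,
        date = cfg$surgery_date + sub$postop_day,
        instrument = ins, score = sc)
    } else {
      wk <- truth[, .(x = mean(.SD[[1]])),
                  by = .(patient_id, week = ceiling(postop_day / 7)),
                  .SDcols = lk$variable]
      wk <- wk[week <= floor(cfg$follow_up_days / 7)]
      p_resp <- cfg$weekly_response_prob[[ins]]
      wk <- wk[runif(nrow(wk)) < p_resp]
      y0 <- lk$c0 + lk$c1 * log(pmax(wk$x, 1e-6))
      if (lk$c1 == 0) {
        eps <- rnorm(nrow(wk), 0, lk$sigma)
      } else {
        e1 <- .orth_noise(wk$x, nrow(wk), 1)
        eps <- .pin_sigma(wk$x, y0, e1, lk) * e1
      }
      sc <- pmin(pmax(round(y0 + eps), lk$range[1]), lk$range[2])
      rows[[ins]] <- data.table(
        patient_id = wk$patient_id,
        date = cfg$surgery_date + 7L * wk$week,
        instrument = ins, score = sc)
    }
  }
  out <- rbindlist(rows)
  setorder(out, patient_id, date, instrument)
  out[]
}
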