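# Synthetic-cohort configuration and calibration. The defaults encode the
# study conditions: a 13-patient two-arm cohort (6 anterior / 7 posterior),
# 70 days of follow-up, GPS duty-cycled 1 min on / 4 min off and
# accelerometer 10 s on / 10 s off, and week-1 / week-5 mobility targets
# with arm-specific recovery (anterior: higher initial level, steeper
# slope). Calibration turns week-level targets into per-day parameter
# curves whose expected week means reproduce the targets exactly.

.WEEK_DAYS <- function(w) (7L * (w - 1L) + 1L):(7L * w)

# Gauss-Hermite nodes/weights (Golub-Welsch); E[f(Z)], Z ~ N(0,1), is
# sum(w * f(sqrt(2) * x)) / sqrt(pi).
.ghq <- function(n = 9) {
  i <- seq_len(n - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- sqrt(i / 2)
  A[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(A, symmetric = TRUE)
  list(z = sqrt(2) * e$values, w = (e$vectors[1, ])^2)
}

.binary_entropy <- function(s) {
  out <- numeric(length(s))
  ok <- s > 0 & s < 1
  out[ok] <- -s[ok] * log(s[ok]) - (1 - s[ok]) * log(1 - s[ok])
  out
}

# log-linear curve exp(a + b d) matching two week means exactly
.solve_loglin <- function(t1, t5, w1 = .WEEK_DAYS(1), w5 = .WEEK_DAYS(5)) {
  f <- function(b) mean(exp(b * w1)) / mean(exp(b * w5)) - t1 / t5
  b <- stats::uniroot(f, c(-0.5, 0.5), tol = 1e-12)$root
  a <- log(t1 / mean(exp(b * w1)))
  c(a = a, b = b)
}

.solve_linear <- function(t1, t5) {
  b <- (t5 - t1) / (mean(.WEEK_DAYS(5)) - mean(.WEEK_DAYS(1)))
  c(a = t1 - mean(.WEEK_DAYS(1)) * b, b = b)
}

# logit-linear visit propensity matching two week-mean propensities
.solve_logit <- function(p1, p5) {
  obj <- function(th) {
    (mean(stats::plogis(th[1] + th[2] * .WEEK_DAYS(1))) - p1)^2 +
      (mean(stats::plogis(th[1] + th[2] * .WEEK_DAYS(5))) - p5)^2
  }
  start <- c(stats::qlogis(p1), (stats::qlogis(p5) - stats::qlogis(p1)) / 28)
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(a = fit$par[1], b = fit$par[2])
}

# Expected day-level entropy given visit propensity pi, mean dwell tau_h
# (hours), observed home hours H, a common lognormal day-dwell multiplier
# (sd sigma on the log scale, floored at min_dwell_h) and up to max_visits
# visits to distinct places. Entropy of home + k equal-dwell visits is
# h(s) + s*log(k), s = k*tau / (k*tau + H).
.expected_entropy <- function(pi_d, tau_h, H_h, sigma, min_dwell_h,
                              max_visits, gh) {
  ks <- seq_len(max_visits)
  pk <- stats::dbinom(ks, max_visits, pi_d)
  tau_z <- pmax(min_dwell_h, tau_h * exp(sigma * gh$z - sigma^2 / 2))
  val_k <- vapply(ks, function(k) {
    s <- k * tau_z / (k * tau_z + H_h)
    sum(gh$w * (.binary_entropy(s) + s * log(k)))
  }, numeric(1))
  sum(pk * val_k)
}

# Dwell curve exp(c + e d) matching week-mean entropy targets
.solve_dwell <- function(e1, e5, pi_curve, home_curve, sigma, min_dwell_h,
                         max_visits, gh) {
  wk_ent <- function(ce, days) {
    mean(vapply(days, function(d) {
      .expected_entropy(stats::plogis(pi_curve[1] + pi_curve[2] * d),
                        exp(ce[1] + ce[2] * d),
                        home_curve[1] + home_curve[2] * d,
                        sigma, min_dwell_h, max_visits, gh)
    }, numeric(1)))
  }
  obj <- function(ce) (wk_ent(ce, .WEEK_DAYS(1)) - e1)^2 +
    (wk_ent(ce, .WEEK_DAYS(5)) - e5)^2
  fit <- stats::optim(c(log(1), 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 4000))
  if (fit$value > 1e-8)
    stop("dwell calibration failed: entropy targets infeasible under the ",
         "configured home-duration and visit-count trajectories")
  c(a = fit$par[1], b = fit$par[2])
}

#' Synthetic post-surgical cohort configuration
#'
#' Builds and calibrates the generator configuration. Week-1 / week-5
#' targets are specified per surgical arm on the raw scale of each mobility
#' variable and turned into day-level parameter curves (log-linear for
#' distance and walking time, linear for home duration, logit-linear for
#' the visit propensity, log-linear for visit dwell calibrated through the
#' entropy expectation). Patient-reported outcomes are linear in the log of
#' the day's (or trailing week's) true mobility with noise solved so the
#' model-implied Pearson correlation hits `prom_targets`.
#'
#' @param n_patients cohort size.
#' @param n_anterior patients in the anterior arm (rest posterior).
#' @param follow_up_days follow-up horizon (days).
#' @param targets nested list of week-1/week-5 raw-scale targets per arm;
#'   see the default for the structure. `steps` targets are raw duty-cycled
#'   daily counts (true steps are `period/on` times larger).
#' @param gps_on_s,gps_off_s,gps_hz GPS duty cycle and within-burst rate.
#' @param accel_on_s,accel_off_s,accel_hz accelerometer duty cycle and rate.
#' @param gps_noise_sd_m isotropic GPS noise (m).
#' @param walk_cadence_hz walking cadence (steps/s).
#' @param step_amp_g walking oscillation amplitude (g).
#' @param accel_noise_sd_g accelerometer noise (g).
#' @param vehicle_speed_ms,walk_speed_ms transit speeds (m/s).
#' @param n_places candidate significant places per patient (besides home).
#' @param place_dist_range_m distance range of places from home (m).
#' @param max_visits maximum distinct places visited per day.
#' @param sd_log_distance,sd_log_distance_patient day/patient lognormal SDs
#'   of distance.
#' @param sd_home_h,sd_home_patient_h day/patient SDs of home hours.
#' @param sd_log_walk,sd_log_walk_patient day/patient lognormal SDs of
#'   walking time.
#' @param sd_log_dwell lognormal SD of the common daily dwell multiplier.
#' @param min_dwell_h floor on per-visit dwell (hours); keeps every visit
#'   above the significant-location qualification threshold.
#' @param loop_stop_s brief stop at the errand-loop turnaround (seconds;
#'   below the significant-location threshold by design).
#' @param day_missing_prob day-level MCAR probability (whole sensor day
#'   absent).
#' @param accel_idle_keep_frac fraction of stationary (gravity-only)
#'   accelerometer bursts retained in the output stream; active bursts are
#'   always kept. Stationary bursts carry no steps, so thinning leaves step
#'   counts untouched while keeping daily coverage for missingness logic.
#' @param vas_response_prob daily VAS response probability.
#' @param weekly_response_prob named response probabilities for the weekly
#'   instruments.
#' @param prom_targets per-instrument linkage: mobility variable, pairing
#'   level, target Pearson correlation, and week-1/week-5 anchor scores.
#' @param surgery_date common surgery date of the simulated cohort.
#' @param timezone IANA timezone of all simulated patients.
#' @return a calibrated list of class `mobiphen_cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 13, n_anterior = 6, follow_up_days = 70,
    targets = default_targets(),
    gps_on_s = 60, gps_off_s = 240, gps_hz = 1,
    accel_on_s = 10, accel_off_s = 10, accel_hz = 10,
    gps_noise_sd_m = 4,
    walk_cadence_hz = 1.8, step_amp_g = 0.3, accel_noise_sd_g = 0.01,
    vehicle_speed_ms = 8, walk_speed_ms = 1.4,
    n_places = 5, place_dist_range_m = c(500, 1200),
    max_visits = 3,
    sd_log_distance = 0.35, sd_log_distance_patient = 0.15,
    sd_home_h = 0.35, sd_home_patient_h = 0.12,
    sd_log_walk = 0.30, sd_log_walk_patient = 0.15,
    sd_log_dwell = 0.25, min_dwell_h = 0.45,
    loop_stop_s = 360,
    day_missing_prob = 0.08,
    accel_idle_keep_frac = 0.02,
    vas_response_prob = 0.5,
    weekly_response_prob = c(mJOA = 0.71, ODI = 0.74, NDI = 0.69),
    prom_targets = default_prom_targets(),
    surgery_date = as.Date("2025-03-02"),
    timezone = "UTC") {
  cfg <- as.list(environment())
  if (n_anterior < 1 || n_anterior >= n_patients)
    stop("cohort config error: arm sizes must be positive and sum to n_patients")
  if (gps_on_s <= 0 || gps_off_s <= 0 || accel_on_s <= 0 || accel_off_s <= 0)
    stop("cohort config error: duty-cycle periods must be positive")
  for (ins in names(prom_targets)) {
    r <- prom_targets[[ins]]$r
    if (abs(r) >= 1) stop("cohort config error: target correlations must lie in (-1, 1)")
  }
  cfg$surgery_date <- as.Date(surgery_date)
  cfg <- .calibrate_curves(cfg)
  cfg <- .calibrate_proms(cfg)
  structure(cfg, class = "mobiphen_cohort_config")
}

#' Default week-1 / week-5 calibration targets
#'
#' Raw-scale week means per arm. Pooled across the 6 anterior / 7 posterior
#' patients these reproduce the reference cohort's week-1 and week-5 means
#' (distance 3.04/13.89 km, home 14.63/14.05 h, count 1.33/2.44, entropy
#' 0.10/0.26 nats, raw steps 108.83/250). The anterior arm starts higher
#' and recovers more steeply for home duration, steps and location count;
#' distance trajectories are shared.
#'
#' @return nested list: `targets[[arm]][[variable]] = c(week1, week5)`.
#' @export
default_targets <- function() {
  list(
    anterior = list(
      distance_km = c(3.04, 13.89),
      home_hours = c(15.1317, 13.2917),
      sig_loc_count = c(1.45, 2.70),
      sig_loc_entropy = c(0.120, 0.300),
      steps = c(160, 260)
    ),
    posterior = list(
      distance_km = c(3.04, 13.89),
      home_hours = c(14.20, 14.70),
      sig_loc_count = c(1.2271, 2.2171),
      sig_loc_entropy = c(0.0829, 0.2257),
      steps = c(64.969, 241.429)
    )
  )
}

#' Default patient-reported-outcome linkage targets
#'
#' Each instrument is linear in the log of one true mobility variable
#' (daily value for VAS, trailing-week mean for the weekly instruments),
#' with anchor scores at weeks 1 and 5 and a target Pearson correlation
#' against the raw-scale variable (VAS-distance -0.358, mJOA-steps 0.403,
#' ODI-distance -0.409, NDI-distance -0.279).
#'
#' @return named list of linkage specifications.
#' @export
default_prom_targets <- function() {
  list(
    VAS = list(variable = "distance_km", level = "daily", r = -0.358,
               anchors = c(5.0, 2.8), range = c(0, 10)),
    mJOA = list(variable = "steps", level = "weekly", r = 0.403,
                anchors = c(13.2, 13.7), range = c(0, 18)),
    ODI = list(variable = "distance_km", level = "weekly", r = -0.409,
               anchors = c(40, 17), range = c(0, 100)),
    NDI = list(variable = "distance_km", level = "weekly", r = -0.279,
               anchors = c(28.4, 16.9), range = c(0, 100))
  )
}

# Turn week targets into per-day parameter curves, per arm.
.calibrate_curves <- function(cfg) {
  gh <- .ghq(9)
  duty_ratio <- (cfg$accel_on_s + cfg$accel_off_s) / cfg$accel_on_s
  curves <- list()
  for (arm in c("anterior", "posterior")) {
    tg <- cfg$targets[[arm]]
    if (any(tg$home_hours > 24))
      stop("cohort config error: home-hours target exceeds 24")
    dist_c <- .solve_loglin(tg$distance_km[1], tg$distance_km[2])
    home_c <- .solve_linear(tg$home_hours[1], tg$home_hours[2])
    # raw step targets -> true walking seconds (duty-cycle capture on/period)
    walk_t <- tg$steps * duty_ratio / cfg$walk_cadence_hz
    walk_c <- .solve_loglin(walk_t[1], walk_t[2])
    p_t <- (tg$sig_loc_count - 1) / cfg$max_visits
    if (any(p_t <= 0 | p_t >= 1))
      stop("cohort config error: count targets must lie in (1, 1 + max_visits)")
    pi_c <- .solve_logit(p_t[1], p_t[2])
    dwell_c <- .solve_dwell(tg$sig_loc_entropy[1], tg$sig_loc_entropy[2],
                            pi_c, home_c, cfg$sd_log_dwell, cfg$min_dwell_h,
                            cfg$max_visits, gh)
    curves[[arm]] <- list(distance = dist_c, home = home_c, walk = walk_c,
                          visit_propensity = pi_c, dwell = dwell_c)
  }
  cfg$curves <- curves
  cfg
}

# Day-level curve values for one arm.
.curve_values <- function(cfg, arm, d) {
  cv <- cfg$curves[[arm]]
  list(
    distance_km = exp(cv$distance[1] + cv$distance[2] * d),
    home_h = cv$home[1] + cv$home[2] * d,
    walk_s = exp(cv$walk[1] + cv$walk[2] * d),
    visit_p = stats::plogis(cv$visit_propensity[1] + cv$visit_propensity[2] * d),
    dwell_h = exp(cv$dwell[1] + cv$dwell[2] * d)
  )
}

# Noise orthogonalized against the linked mobility value (and its log, so
# it is also orthogonal to the linear-in-log mean path), rescaled to an
# exact standard deviation: the sample correlation between score and
# mobility is then pinned by sigma rather than floating with the draw.
.orth_noise <- function(x, n, sigma) {
  e <- rnorm(n)
  if (sigma <= 0) return(rep(0, n))
  if (n >= 5 && stats::sd(x) > 0) {
    e <- stats::lm.fit(cbind(1, x, log(pmax(x, 1e-9))), e)$residuals
  }
  e / stats::sd(e) * sigma
}

# Refine the noise scale against the realized draw: choose sigma so the
# full-sample correlation between the recorded (rounded, truncated) score
# and the linked mobility value equals the calibration target. Rounding to
# a coarse instrument scale perturbs the correlation realization by
# realization; solving on the realized scores removes that wobble.
.pin_sigma <- function(x, y0, e1, lk) {
  if (is.null(lk$r) || lk$c1 == 0 || length(x) < 30) return(lk$sigma)
  r_at <- function(s)
    stats::cor(pmin(pmax(round(y0 + s * e1), lk$range[1]), lk$range[2]), x)
  obj <- function(s) abs(abs(r_at(s)) - abs(lk$r))
  lo <- lk$sigma / 4
  hi <- lk$sigma * 4
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-4)
  if (opt$objective < 0.05) opt$minimum else lk$sigma
}

# Solve the PROM noise SDs so that the correlation between the recorded
# (rounded, range-truncated) score and its linked raw-scale mobility
# variable equals the target. The correlation-vs-sigma map is evaluated on
# a truth-level Monte Carlo sample at a fixed internal seed, with the same
# orthogonalized-noise construction the generator uses, and inverted by
# root finding.
.calibrate_proms <- function(cfg) {
  truth <- simulate_truth(cfg, seed = 999983L, n_rep = 6L)
  truth <- truth[missing == FALSE]
  links <- list()
  for (ins in names(cfg$prom_targets)) {
    tgt <- cfg$prom_targets[[ins]]
    v <- tgt$variable
    if (tgt$level == "daily") {
      x <- truth[[v]]
    } else {
      wk <- truth[, .(x = mean(.SD[[1]])),
                  by = .(rep, patient_id, week = ceiling(postop_day / 7)),
                  .SDcols = v]
      x <- wk$x
    }
    x <- x[x > 0]
    # anchor the linear-in-log-mobility mean path at weeks 1 and 5
    m1 <- .week_curve_mean(cfg, v, 1L)
    m5 <- .week_curve_mean(cfg, v, 5L)
    dlog <- log(m5) - log(m1)
    c1 <- if (abs(dlog) < 1e-6) 0 else
      (tgt$anchors[2] - tgt$anchors[1]) / dlog
    if (!is.finite(c1)) c1 <- 0
    c0 <- tgt$anchors[1] - c1 * log(m1)
    y0 <- c0 + c1 * log(x)
    if (length(x) < 30) {
      # too little observed truth to calibrate against (e.g. near-total
      # missingness); fall back to a nominal noise scale
      links[[ins]] <- list(c0 = c0, c1 = c1, sigma = diff(tgt$range) / 8,
                           variable = v, level = tgt$level,
                           range = tgt$range)
      next
    }
    if (abs(c1) < 1e-12 || abs(tgt$r) < 1e-12) {
      links[[ins]] <- list(c0 = c0, c1 = 0, sigma = diff(tgt$range) / 8,
                           variable = v, level = tgt$level,
                           range = tgt$range)
      next
    }
    e1 <- .with_seed(1000003L, .orth_noise(x, length(x), 1))
    r_at <- function(sigma) {
      yt <- pmin(pmax(round(y0 + sigma * e1), tgt$range[1]), tgt$range[2])
      stats::cor(yt, x)
    }
    r0 <- r_at(1e-3)
    if (abs(tgt$r) >= abs(r0))
      stop("PROM calibration: target correlation for ", ins,
           " is not attainable (max |r| = ", round(abs(r0), 3), ")")
    hi <- 1
    while (abs(r_at(hi)) > abs(tgt$r) && hi < 1024) hi <- hi * 2
    sigma <- stats::uniroot(function(s) abs(r_at(s)) - abs(tgt$r),
                            c(1e-3, hi), tol = 1e-6)$root
    links[[ins]] <- list(c0 = c0, c1 = c1, sigma = sigma, r = tgt$r,
                         variable = v, level = tgt$level, range = tgt$range)
  }
  cfg$prom_links <- links
  cfg
}

# Pooled expected week mean of a variable from the calibrated curves
# (true scale; steps on the true-step scale).
.week_curve_mean <- function(cfg, variable, week) {
  days <- .WEEK_DAYS(week)
  n_arm <- c(anterior = cfg$n_anterior,
             posterior = cfg$n_patients - cfg$n_anterior)
  tot <- 0
  for (arm in names(n_arm)) {
    cvv <- .curve_values(cfg, arm, days)
    val <- switch(variable,
      distance_km = mean(cvv$distance_km),
      home_hours = mean(cvv$home_h),
      steps = mean(cvv$walk_s) * cfg$walk_cadence_hz,
      sig_loc_count = 1 + cfg$max_visits * mean(cvv$visit_p),
      stop("no curve mean for variable ", variable))
    tot <- tot + n_arm[[arm]] * val
  }
  tot / cfg$n_patients
}

#' @export
print.mobiphen_cohort_config <- function(x, ...) {
  cat("<mobiphen cohort configuration>\n")
  cat("  ", x$n_patients, " patients (", x$n_anterior, " anterior / ",
      x$n_patients - x$n_anterior, " posterior), ", x$follow_up_days,
      "-day follow-up\n", sep = "")
  cat("  GPS ", x$gps_on_s, "s on / ", x$gps_off_s, "s off at ", x$gps_hz,
      " Hz; accel ", x$accel_on_s, "s on / ", x$accel_off_s, "s off at ",
      x$accel_hz, " Hz\n", sep = "")
  invisible(x)
}
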