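# Cohort-level feature extraction: raw sensor streams -> one row of the
# five mobility variables per patient-day. GPS features are computed on
# epoch-averaged positions; significant locations are clustered per patient
# over the whole follow-up; day boundaries are midnight-to-midnight in the
# patient's timezone.

# Epoch seconds of local midnight for postop days 1..n_days+1 (interval
# boundaries), DST-correct.
.day_boundaries <- function(surgery_date, tz, n_days) {
  as.numeric(as.POSIXct(paste(surgery_date + seq_len(n_days + 1), "00:00:00"),
                        tz = tz))
}

#' Summarize one day of GPS data into the four location variables
#'
#' Convenience wrapper composing pause segmentation, flight extraction and
#' the occupancy profile for a single day given the patient's significant
#' locations and home. A day with no points yields all-missing fields.
#'
#' @param day_points one day's GPS fixes (`t`, `lat`, `lon`), raw or
#'   epoch-averaged.
#' @param sig_locs the patient's significant locations (may be empty).
#' @param home the home row of `sig_locs`, or `NULL`.
#' @param config a [run_config()].
#' @return list with `distance_km`, `home_hours`, `sig_loc_count`,
#'   `sig_loc_entropy`.
#' @export
summarize_day <- function(day_points, sig_locs, home, config = run_config()) {
  if (is.null(day_points) || nrow(day_points) == 0)
    return(list(distance_km = NA_real_, home_hours = NA_real_,
                sig_loc_count = NA_integer_, sig_loc_entropy = NA_real_))
  ep <- epoch_positions(day_points, config$epoch_s)
  pauses <- segment_pauses(ep, config$pause_radius_m, config$min_pause_s,
                           config$gap_max_s, config$epoch_s)
  flights <- extract_flights(ep, pauses, config$heading_change_deg)
  if (is.null(sig_locs) || nrow(sig_locs) == 0) {
    return(list(distance_km = daily_distance_km(flights),
                home_hours = NA_real_, sig_loc_count = 0L,
                sig_loc_entropy = 0))
  }
  prof <- day_location_profile(pauses, sig_locs, config$sig_loc_separation_m)
  list(distance_km = daily_distance_km(flights),
       home_hours = if (is.null(home)) NA_real_ else
         daily_home_duration_h(pauses, home, config$sig_loc_separation_m),
       sig_loc_count = prof$count,
       sig_loc_entropy = entropy_nats(prof$p))
}

#' Extract daily mobility summaries for a whole cohort
#'
#' Runs the full GPS and accelerometer feature extraction per patient:
#' epoch averaging, pause/flight segmentation and daily distance,
#' follow-up-level significant-location clustering, home detection, daily
#' occupancy profiles, and duty-cycled step counting. Days whose GPS
#' coverage falls below `min_onwindow_fraction` of the expected on-windows
#' (and days with no data at all) get missing GPS fields; days with no
#' accelerometer bursts get missing steps.
#'
#' @param cohort a `mobiphen_cohort` ([read_cohort()] or
#'   [simulate_cohort()]).
#' @param config a [run_config()].
#' @param artifacts logical; attach per-patient pauses, flights and
#'   significant locations as the `"artifacts"` attribute.
#' @return a `data.table`: `patient_id`, `postop_day` (1..last observed
#'   day), the five mobility variables.
#' @export
extract_daily_summaries <- function(cohort, config = run_config(),
                                    artifacts = FALSE) {
  stopifnot(inherits(cohort, "mobiphen_cohort"))
  patients <- cohort$patients
  gps_period <- config$gps_cycle_on_s + config$gps_cycle_off_s
  acc_period <- config$accel_cycle_on_s + config$accel_cycle_off_s
  out <- vector("list", nrow(patients))
  art <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    tz <- patients$timezone[i]
    sdate <- as.Date(patients$surgery_date[i])
    g <- cohort$gps[[pid]]
    a <- cohort$accel[[pid]]
    if (is.finite(config$accuracy_max_m) && nrow(g) > 0)
      g <- g[is.na(accuracy) | accuracy <= config$accuracy_max_m]
    t_max <- suppressWarnings(max(c(g$t, a$t)))
    if (!is.finite(t_max)) {
      out[[i]] <- data.table(patient_id = pid, postop_day = 1L,
                             distance_km = NA_real_, home_hours = NA_real_,
                             sig_loc_count = NA_integer_,
                             sig_loc_entropy = NA_real_, steps = NA_integer_)
      next
    }
    day1 <- as.numeric(as.POSIXct(paste(sdate + 1, "00:00:00"), tz = tz))
    n_days <- max(1L, ceiling((t_max - day1) / 86400) + 1L)
    bounds <- .day_boundaries(sdate, tz, n_days)
    n_days <- length(bounds) - 1L

    ep <- epoch_positions(g, config$epoch_s)
    ep_day <- findInterval(ep$t, bounds)
    pauses_by_day <- vector("list", n_days)
    dist_by_day <- rep(NA_real_, n_days)
    cover_by_day <- rep(0, n_days)
    for (d in seq_len(n_days)) {
      pts <- ep[ep_day == d]
      if (nrow(pts) == 0) next
      sod <- pts$t - bounds[d]
      cover_by_day[d] <- length(unique(floor(sod / gps_period))) /
        (86400 / gps_period)
      if (cover_by_day[d] < config$min_onwindow_fraction) next
      pp <- segment_pauses(pts, config$pause_radius_m, config$min_pause_s,
                           config$gap_max_s, config$epoch_s)
      fl <- extract_flights(pts, pp, config$heading_change_deg)
      pauses_by_day[[d]] <- pp
      dist_by_day[d] <- daily_distance_km(fl)
    }
    all_pauses <- rbindlist(Filter(Negate(is.null), pauses_by_day))
    sig <- find_significant_locations(all_pauses, config$sig_loc_min_pause_s,
                                      config$sig_loc_separation_m,
                                      seed = config$seed + i)
    home <- NULL
    if (nrow(sig) > 0) {
      sig <- detect_home(sig, all_pauses, config$sig_loc_separation_m, tz)
      home <- sig[is_home == TRUE]
    }

    steps_by_day <- rep(NA_integer_, n_days)
    if (nrow(a) > 0) {
      a_day <- findInterval(a$t, bounds)
      for (d in unique(a_day[a_day >= 1 & a_day <= n_days])) {
        steps_by_day[d] <- daily_steps(
          a[a_day == d], config$step_params,
          config$accel_cycle_on_s, config$accel_cycle_off_s,
          extrapolate = config$steps_extrapolate)
      }
    }

    rows <- data.table(patient_id = pid, postop_day = seq_len(n_days),
                       distance_km = NA_real_, home_hours = NA_real_,
                       sig_loc_count = NA_integer_,
                       sig_loc_entropy = NA_real_,
                       steps = steps_by_day)
    for (d in seq_len(n_days)) {
      if (is.na(dist_by_day[d])) next
      pp <- pauses_by_day[[d]]
      rows[d, distance_km := dist_by_day[d]]
      if (nrow(sig) > 0) {
        prof <- day_location_profile(pp, sig, config$sig_loc_separation_m)
        rows[d, `:=`(
          home_hours = daily_home_duration_h(pp, home, config$sig_loc_separation_m),
          sig_loc_count = prof$count,
          sig_loc_entropy = entropy_nats(prof$p))]
      } else {
        rows[d, `:=`(home_hours = NA_real_, sig_loc_count = 0L,
                     sig_loc_entropy = 0)]
      }
    }
    out[[i]] <- rows
    if (artifacts)
      art[[pid]] <- list(pauses = all_pauses, sig_locs = sig)
  }
  res <- rbindlist(out)
  setorder(res, patient_id, postop_day)
  if (artifacts) data.table::setattr(res, "artifacts", art)
  res[]
}
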