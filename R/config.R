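# Pipeline run configuration. Defaults house the study constants: 15-min /
# 50-m significant-location rule, 70-day censoring, 50% sparse-variable rule,
# m = 5 imputations over 50 chained iterations.

#' Pipeline run configuration
#'
#' Builds the configuration object consumed by the extraction, preprocessing
#' and analysis stages. Every argument has a default; pass only what you want
#' to override. `run_config(yaml = "run.yaml")` merges overrides from a YAML
#' file (keys mirror the argument names) before applying `...` overrides.
#'
#' @param pause_radius_m radius (m) a device must stay within for a pause.
#' @param min_pause_s minimum pause duration in seconds.
#' @param sig_loc_min_pause_s minimum pause duration (s) for a pause to enter
#'   significant-location clustering (15 min).
#' @param sig_loc_separation_m minimum separation (m) between significant
#'   locations, also the attribution radius for daily occupancy.
#' @param heading_change_deg heading change (degrees) that splits a flight.
#' @param epoch_s positions are averaged over epochs of this length (s)
#'   before segmentation, to suppress per-fix GPS noise.
#' @param gap_max_s observation gaps longer than this (s) split a pause so
#'   unobserved time is never counted as dwell.
#' @param min_onwindow_fraction a day with fewer than this fraction of its
#'   expected GPS on-windows observed is treated as missing.
#' @param accuracy_max_m drop fixes with reported accuracy above this (m);
#'   `Inf` keeps everything (default).
#' @param gps_cycle_on_s,gps_cycle_off_s GPS duty cycle (60 s on / 240 s off).
#' @param accel_cycle_on_s,accel_cycle_off_s accelerometer duty cycle
#'   (10 s on / 10 s off).
#' @param step_params a [step_params()] list for the step detector.
#' @param steps_extrapolate logical; scale daily step sums by the accel duty
#'   cycle period/on ratio to account for off-windows. Default `FALSE`.
#' @param censor_day follow-up horizon in post-operative days.
#' @param missing_fraction_threshold per-patient missing fraction above which
#'   a variable is excluded from analysis (strictly greater than).
#' @param mice_m,mice_iterations,mice_trees chained-imputation settings:
#'   number of completed datasets, chained iterations, forest size.
#' @param outlier_k Tukey fence multiplier for automated outlier removal.
#' @param log_variables variables receiving a log(x + 1) companion column.
#' @param fdr_method multiplicity adjustment tag passed to [stats::p.adjust].
#' @param gamma_offset positive offset added to zeros when fitting
#'   gamma-family trajectories.
#' @param seed integer seed for the stochastic stages (imputation,
#'   clustering restarts).
#' @param yaml optional path to a YAML file of overrides.
#' @param ... named overrides applied after the YAML file.
#' @return a list of class `mobiphen_config`.
#' @export
run_config <- function(pause_radius_m = 50,
                       min_pause_s = 300,
                       sig_loc_min_pause_s = 900,
                       sig_loc_separation_m = 50,
                       heading_change_deg = 30,
                       epoch_s = 10,
                       gap_max_s = 900,
                       min_onwindow_fraction = 0.1,
                       accuracy_max_m = Inf,
                       gps_cycle_on_s = 60,
                       gps_cycle_off_s = 240,
                       accel_cycle_on_s = 10,
                       accel_cycle_off_s = 10,
                       step_params = mobiphen::step_params(),
                       steps_extrapolate = FALSE,
                       censor_day = 70,
                       missing_fraction_threshold = 0.5,
                       mice_m = 5,
                       mice_iterations = 50,
                       mice_trees = 100,
                       outlier_k = 3,
                       log_variables = c("distance_km", "steps", "sig_loc_entropy"),
                       fdr_method = "BH",
                       gamma_offset = 0.01,
                       seed = 1L,
                       yaml = NULL,
                       ...) {
  cfg <- as.list(environment())
  cfg$yaml <- NULL
  if (!is.null(yaml)) {
    overrides <- yaml::read_yaml(yaml)
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  pos <- c("pause_radius_m", "min_pause_s", "sig_loc_min_pause_s",
           "sig_loc_separation_m", "heading_change_deg", "epoch_s",
           "gap_max_s", "gps_cycle_on_s", "gps_cycle_off_s",
           "accel_cycle_on_s", "accel_cycle_off_s", "censor_day",
           "mice_m", "mice_iterations", "outlier_k", "gamma_offset")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("config field '", k, "' must be a strictly positive scalar")
  }
  if (cfg$missing_fraction_threshold <= 0 || cfg$missing_fraction_threshold >= 1)
    stop("missing_fraction_threshold must lie in (0, 1)")
  cfg$step_params <- do.call(step_params, cfg$step_params[
    intersect(names(cfg$step_params),
              names(formals(step_params)))])
  structure(cfg, class = "mobiphen_config")
}

#' Echo the effective configuration to a YAML file
#'
#' @param cfg a `mobiphen_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$step_params <- unclass(out$step_params)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.mobiphen_config <- function(x, ...) {
  cat("<mobiphen run configuration>\n")
  cat("  pauses: radius", x$pause_radius_m, "m, min", x$min_pause_s, "s;",
      "significant locations:", x$sig_loc_min_pause_s, "s /",
      x$sig_loc_separation_m, "m\n")
  cat("  censoring day", x$censor_day, "| sparse rule >",
      x$missing_fraction_threshold, "| imputation m =", x$mice_m,
      "x", x$mice_iterations, "iterations\n")
  invisible(x)
}

.log_msg <- function(...) {
  if (isTRUE(getOption("mobiphen.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(...))
}
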