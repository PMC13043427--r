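# CSV readers/writers for all pipeline schemas. Column naming is tolerant of
# Beiwe-style raw exports ("timestamp, UTC time, latitude, longitude,
# altitude, accuracy"): only timestamp/latitude/longitude are required and
# extra columns are ignored. Malformed rows are dropped and counted, never
# fatal -- sensor exports are dirty and sparse patients are handled by the
# 50%-missingness rule downstream.

.norm_names <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

.require_cols <- function(dt, cols, what, path) {
  missing <- setdiff(cols, names(dt))
  if (length(missing))
    stop(sprintf("%s schema error in '%s': missing column(s) %s",
                 what, path, paste(missing, collapse = ", ")))
}

#' Read a raw GPS trace CSV
#'
#' Expects at least `timestamp` (UTC seconds, fractional allowed), `latitude`
#' and `longitude` columns; an `accuracy` column (meters) is kept when
#' present. Rows with non-finite fields or out-of-range coordinates are
#' dropped with a message reporting the count; points are sorted by time and
#' duplicate timestamps collapse to their first row.
#'
#' @param path CSV file path.
#' @return a `data.table` with columns `t`, `lat`, `lon`, `accuracy`.
#' @export
read_gps_csv <- function(path) {
  if (!file.exists(path)) stop("GPS file not found: ", path)
  dt <- fread(path, showProgress = FALSE)
  if (nrow(dt) == 0) {
    warning("empty GPS file: ", path)
    return(data.table(t = numeric(), lat = numeric(), lon = numeric(),
                      accuracy = numeric()))
  }
  setnames(dt, .norm_names(names(dt)))
  .require_cols(dt, c("timestamp", "latitude", "longitude"), "GPS", path)
  out <- data.table(
    t = suppressWarnings(as.numeric(dt$timestamp)),
    lat = suppressWarnings(as.numeric(dt$latitude)),
    lon = suppressWarnings(as.numeric(dt$longitude)),
    accuracy = if ("accuracy" %in% names(dt))
      suppressWarnings(as.numeric(dt$accuracy)) else NA_real_
  )
  ok <- is.finite(out$t) & is.finite(out$lat) & is.finite(out$lon) &
    out$lat >= -90 & out$lat <= 90 & out$lon >= -180 & out$lon <= 180
  n_bad <- sum(!ok)
  if (n_bad > 0) .log_msg("read_gps_csv: dropped %d malformed row(s) in %s",
                          n_bad, basename(path))
  out <- out[ok]
  setorder(out, t)
  out <- out[!duplicated(t)]
  out[]
}

#' Read a raw accelerometer CSV
#'
#' Requires `timestamp`, `x`, `y`, `z` columns (acceleration in g). Rows with
#' non-finite values are dropped with a logged count; samples are sorted by
#' time.
#'
#' @param path CSV file path.
#' @return a `data.table` with columns `t`, `x`, `y`, `z`.
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) stop("accelerometer file not found: ", path)
  dt <- fread(path, showProgress = FALSE)
  if (nrow(dt) == 0) {
    warning("empty accelerometer file: ", path)
    return(data.table(t = numeric(), x = numeric(), y = numeric(),
                      z = numeric()))
  }
  setnames(dt, .norm_names(names(dt)))
  .require_cols(dt, c("timestamp", "x", "y", "z"), "accelerometer", path)
  out <- data.table(
    t = suppressWarnings(as.numeric(dt$timestamp)),
    x = suppressWarnings(as.numeric(dt$x)),
    y = suppressWarnings(as.numeric(dt$y)),
    z = suppressWarnings(as.numeric(dt$z))
  )
  ok <- is.finite(out$t) & is.finite(out$x) & is.finite(out$y) & is.finite(out$z)
  n_bad <- sum(!ok)
  if (n_bad > 0) .log_msg("read_accel_csv: dropped %d malformed row(s) in %s",
                          n_bad, basename(path))
  out <- out[ok]
  setorder(out, t)
  out[]
}

#' Read the patient-metadata table
#'
#' @param path path to `patients.csv` with columns `patient_id`, `age`,
#'   `sex` (F/M), `approach` (anterior/posterior), `levels`,
#'   `instrumentation`, `surgery_date` (ISO date), `timezone` (IANA name).
#' @return a `data.table`, one row per patient.
#' @export
read_patients_csv <- function(path) {
  if (!file.exists(path)) stop("patients file not found: ", path)
  dt <- fread(path, showProgress = FALSE, colClasses = list(character = "patient_id"))
  setnames(dt, .norm_names(names(dt)))
  .require_cols(dt, c("patient_id", "approach", "surgery_date"), "patients", path)
  dt[, patient_id := as.character(patient_id)]
  bad <- setdiff(unique(dt$approach), c("anterior", "posterior"))
  if (length(bad))
    stop("patients integrity error: approach must be anterior/posterior, got ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(dt$patient_id))
    stop("patients integrity error: duplicate patient_id")
  if (!"timezone" %in% names(dt)) dt[, timezone := "UTC"]
  dt[, surgery_date := as.Date(surgery_date)]
  dt[]
}

#' Read the patient-reported-outcome long table
#'
#' Validates instrument names and native scales (VAS 0-10, mJOA 0-18,
#' ODI/NDI 0-100 percent).
#'
#' @param path path to `proms.csv` with columns `patient_id`, `date`,
#'   `instrument`, `score`.
#' @return a `data.table`.
#' @export
read_proms_csv <- function(path) {
  if (!file.exists(path)) stop("PROMs file not found: ", path)
  dt <- fread(path, showProgress = FALSE, colClasses = list(character = "patient_id"))
  setnames(dt, .norm_names(names(dt)))
  .require_cols(dt, c("patient_id", "date", "instrument", "score"), "PROMs", path)
  dt[, `:=`(patient_id = as.character(patient_id), date = as.Date(date),
            instrument = as.character(instrument),
            score = as.numeric(score))]
  bad <- setdiff(unique(dt$instrument), c("VAS", "mJOA", "ODI", "NDI"))
  if (length(bad))
    stop("PROMs schema error: unknown instrument(s) ", paste(bad, collapse = ", "))
  lims <- list(VAS = c(0, 10), mJOA = c(0, 18), ODI = c(0, 100), NDI = c(0, 100))
  for (ins in names(lims)) {
    s <- dt[instrument == ins, score]
    if (length(s) && (any(!is.finite(s)) || any(s < lims[[ins]][1]) ||
                      any(s > lims[[ins]][2])))
      stop("PROMs integrity error: ", ins, " score outside ",
           lims[[ins]][1], "-", lims[[ins]][2])
  }
  dt[]
}

.read_stream_dir <- function(dir, pid, reader) {
  cand_file <- file.path(dir, paste0(pid, ".csv"))
  cand_dir <- file.path(dir, pid)
  if (file.exists(cand_file)) return(reader(cand_file))
  if (dir.exists(cand_dir)) {
    files <- sort(list.files(cand_dir, pattern = "\\.csv$", full.names = TRUE))
    if (length(files)) {
      out <- rbindlist(lapply(files, reader))
      setorder(out, t)
      return(out)
    }
  }
  NULL
}

#' Read a full cohort directory
#'
#' Expects `patients.csv`, `proms.csv` and per-patient sensor streams under
#' `gps/` and `accel/` (either `<patient_id>.csv` or a `<patient_id>/`
#' subdirectory of chunked CSVs). Every patient listed in `patients.csv` gets
#' (possibly empty, with a warning) streams; PROM rows referencing unknown
#' patients are an integrity error.
#'
#' @param dir cohort directory.
#' @return a list of class `mobiphen_cohort` with elements `patients`,
#'   `proms`, `gps` (named list of data.tables), `accel` (named list).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  patients <- read_patients_csv(file.path(dir, "patients.csv"))
  proms_path <- file.path(dir, "proms.csv")
  proms <- if (file.exists(proms_path)) read_proms_csv(proms_path) else
    data.table(patient_id = character(), date = as.Date(character()),
               instrument = character(), score = numeric())
  unknown <- setdiff(unique(proms$patient_id), patients$patient_id)
  if (length(unknown))
    stop("cohort integrity error: proms.csv references unknown patient(s): ",
         paste(unknown, collapse = ", "))
  gps <- list(); accel <- list()
  for (pid in patients$patient_id) {
    g <- .read_stream_dir(file.path(dir, "gps"), pid, read_gps_csv)
    if (is.null(g)) {
      warning("patient ", pid, " has no GPS data; attaching empty stream")
      g <- data.table(t = numeric(), lat = numeric(), lon = numeric(),
                      accuracy = numeric())
    }
    a <- .read_stream_dir(file.path(dir, "accel"), pid, read_accel_csv)
    if (is.null(a)) {
      warning("patient ", pid, " has no accelerometer data; attaching empty stream")
      a <- data.table(t = numeric(), x = numeric(), y = numeric(), z = numeric())
    }
    gps[[pid]] <- g
    accel[[pid]] <- a
  }
  structure(list(patients = patients, proms = proms, gps = gps, accel = accel),
            class = "mobiphen_cohort")
}

.summary_cols <- c("distance_km", "home_hours", "sig_loc_count",
                   "sig_loc_entropy", "steps")

#' Write daily mobility summaries to CSV
#'
#' One row per patient-day with the five mobility variables. Duplicate
#' (patient, day) pairs are an error; the file round-trips losslessly through
#' [read_daily_summaries()].
#'
#' @param rows a data.frame/data.table of daily summaries.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_summaries <- function(rows, path) {
  rows <- as.data.table(rows)
  if (nrow(rows) == 0) stop("write_daily_summaries: empty table")
  .require_cols(rows, c("patient_id", "postop_day", .summary_cols),
                "daily summaries", path)
  if (anyDuplicated(rows[, .(patient_id, postop_day)]))
    stop("write_daily_summaries: duplicate (patient_id, postop_day) row(s)")
  fwrite(rows[, c("patient_id", "postop_day", .summary_cols), with = FALSE],
         path)
  invisible(path)
}

#' Read daily mobility summaries from CSV
#'
#' @param path CSV written by [write_daily_summaries()].
#' @return a `data.table` keyed by patient and day.
#' @export
read_daily_summaries <- function(path) {
  if (!file.exists(path)) stop("daily summaries file not found: ", path)
  dt <- fread(path, showProgress = FALSE, colClasses = list(character = "patient_id"))
  .require_cols(dt, c("patient_id", "postop_day", .summary_cols),
                "daily summaries", path)
  dt[, patient_id := as.character(patient_id)]
  if (anyDuplicated(dt[, .(patient_id, postop_day)]))
    stop("read_daily_summaries: duplicate (patient_id, postop_day) row(s)")
  setorder(dt, patient_id, postop_day)
  dt[]
}

#' Write a simulated cohort to a directory in the cohort CSV layout
#'
#' Produces `patients.csv`, `proms.csv`, `gps/<id>.csv`, `accel/<id>.csv`
#' and, when ground truth is attached, `ground_truth.csv`.
#'
#' @param cohort a `mobiphen_cohort` (e.g. from [simulate_cohort()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mobiphen_cohort"))
  dir.create(file.path(dir, "gps"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "accel"), recursive = TRUE, showWarnings = FALSE)
  fwrite(cohort$patients, file.path(dir, "patients.csv"))
  fwrite(cohort$proms, file.path(dir, "proms.csv"))
  for (pid in names(cohort$gps)) {
    g <- cohort$gps[[pid]]
    fwrite(data.table(timestamp = g$t, latitude = g$lat, longitude = g$lon,
                      accuracy = g$accuracy),
           file.path(dir, "gps", paste0(pid, ".csv")))
  }
  for (pid in names(cohort$accel)) {
    a <- cohort$accel[[pid]]
    fwrite(data.table(timestamp = a$t, x = a$x, y = a$y, z = a$z),
           file.path(dir, "accel", paste0(pid, ".csv")))
  }
  if (!is.null(cohort$truth))
    fwrite(cohort$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
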