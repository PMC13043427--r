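# Daily step counts from duty-cycled tri-axial accelerometer bursts. The
# detector is a transparent threshold-peak counter on the band-passed
# acceleration magnitude: orientation-invariant, parameterized, and cheap
# enough to screen thousands of 10-second bursts per day.

#' Step-detector parameters
#'
#' @param bandpass_low_hz,bandpass_high_hz passband (Hz) of the 2nd-order
#'   Butterworth filter applied to the magnitude series; the default
#'   0.5-3 Hz brackets human walking cadence.
#' @param peak_threshold_g minimum filtered-magnitude excursion (g) for a
#'   peak to count as a step.
#' @param min_peak_interval_s refractory period between accepted peaks (s).
#' @return a list of class `step_params`.
#' @export
step_params <- function(bandpass_low_hz = 0.5, bandpass_high_hz = 3.0,
                        peak_threshold_g = 0.1, min_peak_interval_s = 0.3) {
  stopifnot(bandpass_low_hz > 0, bandpass_high_hz > bandpass_low_hz,
            peak_threshold_g > 0, min_peak_interval_s > 0)
  structure(list(bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 peak_threshold_g = peak_threshold_g,
                 min_peak_interval_s = min_peak_interval_s),
            class = "step_params")
}

#' Acceleration magnitude series
#'
#' \eqn{\sqrt{x^2+y^2+z^2}} per sample, in g. Invariant under device
#' re-orientation.
#'
#' @param samples a `data.table` with columns `t`, `x`, `y`, `z`.
#' @return a `data.table` with `t` and `mag`.
#' @export
magnitude_series <- function(samples) {
  samples <- as.data.table(samples)
  data.table(t = samples$t,
             mag = sqrt(samples$x^2 + samples$y^2 + samples$z^2))
}

#' Count steps in one on-window burst
#'
#' Band-passes the magnitude series and counts peaks exceeding the
#' threshold, separated by at least the refractory interval. Bursts whose
#' magnitude never deviates from baseline by half the threshold are
#' short-circuited to zero without filtering.
#'
#' @param mag magnitude values (g) of a single burst, evenly sampled.
#' @param fs sampling rate in Hz; must be known and positive.
#' @param params a [step_params()] list.
#' @return integer step count.
#' @export
count_steps_burst <- function(mag, fs, params = step_params()) {
  if (missing(fs) || !is.finite(fs) || fs <= 0)
    stop("count_steps_burst: unknown sampling rate")
  n <- length(mag)
  if (n < 2) return(0L)
  if (max(abs(mag - mean(mag))) < params$peak_threshold_g / 2) return(0L)
  ny <- fs / 2
  hi <- min(params$bandpass_high_hz, 0.95 * ny)
  bf <- signal::butter(2, c(params$bandpass_low_hz, hi) / ny, type = "pass")
  f <- signal::filtfilt(bf, mag - mean(mag))
  thr <- params$peak_threshold_g
  is_peak <- which(f[-c(1, n)] >= f[-c(n - 1, n)] & f[-c(1, n)] > f[-(1:2)] &
                   f[-c(1, n)] > thr) + 1L
  if (!length(is_peak)) return(0L)
  min_gap <- params$min_peak_interval_s * fs
  kept <- is_peak[1]
  last <- is_peak[1]
  for (i in is_peak[-1]) {
    if (i - last >= min_gap) {
      kept <- c(kept, i)
      last <- i
    }
  }
  length(kept)
}

#' Daily step count from duty-cycled bursts
#'
#' Splits a day's samples into duty-cycle bursts, counts steps per burst and
#' sums. With `extrapolate = TRUE` the sum is scaled by (cycle period /
#' on-window) to account for steps taken while the sensor was off; the
#' default reports the raw observed sum.
#'
#' @param samples one patient-day of accelerometer samples (`t`, `x`, `y`,
#'   `z`), timestamps in seconds.
#' @param params a [step_params()] list.
#' @param cycle_on_s,cycle_off_s duty cycle (10 s on / 10 s off by default).
#' @param extrapolate logical; scale for off-windows.
#' @return integer step count, or `NA` when the day has no bursts.
#' @export
daily_steps <- function(samples, params = step_params(),
                        cycle_on_s = 10, cycle_off_s = 10,
                        extrapolate = FALSE) {
  samples <- as.data.table(samples)
  if (nrow(samples) == 0) return(NA_integer_)
  period <- cycle_on_s + cycle_off_s
  mg <- magnitude_series(samples)
  mg[, burst := floor(t / period)]
  # cheap variance screen: bursts that never leave baseline count zero
  stats_b <- mg[, .(n = .N, dev = max(abs(mag - mean(mag))), t0 = min(t),
                    t1 = max(t)), by = burst]
  thr <- params$peak_threshold_g / 2
  active <- stats_b[n >= 4 & dev >= thr, burst]
  total <- 0L
  for (b in active) {
    v <- mg[burst == b, mag]
    span <- stats_b[burst == b, t1 - t0]
    fs <- if (span > 0) (length(v) - 1) / span else NA_real_
    total <- total + count_steps_burst(v, fs, params)
  }
  if (extrapolate) total <- as.integer(round(total * period / cycle_on_s))
  as.integer(total)
}
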