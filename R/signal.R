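#' Signal-preparation configuration
#'
#' Settings for turning a raw device trace into a gravity-free, uniformly
#' sampled linear-acceleration trace.
#'
#' @param resample_rate_hz Target uniform sampling rate in Hz. Phone sensors
#'   sample irregularly; integration and filtering need a uniform grid.
#' @param rest_window_s Length in seconds of the pre-stimulus window used to
#'   estimate the resting (gravity) baseline. Trials start with the phone at
#'   rest, so this window contains gravity plus sensor noise only.
#' @param lowpass_hz Zero-phase low-pass cutoff in Hz applied before onset
#'   detection, or `NULL` to disable. Hand tremor and sensor noise would
#'   otherwise trip a fixed 0.8 m/s^2 onset threshold; a zero-phase filter
#'   removes them without shifting the onset.
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(resample_rate_hz = 100, rest_window_s = 0.3,
                        lowpass_hz = 20) {
  stopifnot(resample_rate_hz > 0, rest_window_s > 0)
  if (!is.null(lowpass_hz)) {
    stopifnot(lowpass_hz > 0, lowpass_hz < resample_rate_hz / 2)
  }
  structure(list(resample_rate_hz = resample_rate_hz,
                 rest_window_s = rest_window_s,
                 lowpass_hz = lowpass_hz),
            class = "prep_config")
}

#' Estimate the resting acceleration baseline before stimulus onset
#'
#' Per-axis mean acceleration over the window `[stim_onset - rest_window,
#' stim_onset]`. With a plain accelerometer the baseline is the gravity vector
#' in the device frame (norm near 9.81 m/s^2); with a linear accelerometer
#' (gravity already removed on-device) it is near zero.
#'
#' @param trace Trace tibble (`t`, `ax`, `ay`, `az`).
#' @param stim_onset Stimulus onset in seconds on the trace clock.
#' @param cfg A [prep_config()].
#' @return Named numeric 3-vector `c(ax, ay, az)` in m/s^2.
#' @export
estimate_rest_baseline <- function(trace, stim_onset, cfg = prep_config()) {
  in_win <- trace$t >= (stim_onset - cfg$rest_window_s) & trace$t <= stim_onset
  if (sum(in_win) < 5L) {
    abort(sprintf(
      "only %d samples in the %.2f s rest window before stimulus onset (need >= 5)",
      sum(in_win), cfg$rest_window_s), class = "maatkit_baseline_error")
  }
  c(ax = mean(trace$ax[in_win]),
    ay = mean(trace$ay[in_win]),
    az = mean(trace$az[in_win]))
}

#' Remove the constant gravity baseline from a trace
#'
#' Subtracts the baseline vector sample-wise. Gravity is treated as constant
#' over a trial: mAAT strokes last well under a second and the participant
#' holds the phone still before each stimulus, so full orientation tracking
#' is unnecessary. When the device already removed gravity
#' (`has_linear_accelerometer`), pass `identity = TRUE` to skip subtraction.
#'
#' @inheritParams estimate_rest_baseline
#' @param baseline 3-vector from [estimate_rest_baseline()].
#' @param identity If `TRUE`, return the trace unchanged.
#' @return The trace with `ax`, `ay`, `az` replaced by linear acceleration.
#' @export
remove_gravity <- function(trace, baseline, identity = FALSE) {
  if (identity) return(trace)
  trace$ax <- trace$ax - baseline[[1L]]
  trace$ay <- trace$ay - baseline[[2L]]
  trace$az <- trace$az - baseline[[3L]]
  trace
}

#' Resample a trace onto a uniform time grid
#'
#' Linear interpolation onto a grid starting at the first timestamp and
#' stepping at `rate` Hz up to the last timestamp (a remainder shorter than
#' one step is dropped so the grid stays exactly uniform). Interpolation is
#' linear rather than spline so that there is no overshoot near the sharp
#' movement-onset edge. The operation is idempotent on its own output.
#'
#' @param trace Trace tibble.
#' @param rate Grid rate in Hz.
#' @return Trace tibble on the uniform grid.
#' @export
resample_uniform <- function(trace, rate = 100) {
  stopifnot(nrow(trace) >= 2L, rate > 0)
  span <- trace$t[nrow(trace)] - trace$t[1L]
  if (span < 2 / rate) {
    abort(sprintf("trace span %.4f s shorter than two grid steps at %g Hz",
                  span, rate), class = "maatkit_signal_error")
  }
  # a sub-step remainder at the tail is dropped to keep the grid exactly
  # uniform (required by the integrators); traces end at rest by design
  n_steps <- floor(span * rate + 1e-9)
  grid <- trace$t[1L] + seq(0L, n_steps) / rate
  out <- tibble::tibble(t = grid)
  for (col in setdiff(names(trace), "t")) {
    out[[col]] <- stats::approx(trace$t, trace[[col]], xout = grid,
                                rule = 2)$y
  }
  out
}

#' Zero-phase low-pass filter on a uniformly sampled trace
#'
#' Butterworth filter applied forward and backward (`signal::filtfilt`), so
#' the effective response is 4th order and the phase shift is zero --
#' filtering does not move the motion onset in time.
#'
#' @param trace Uniform-grid trace tibble.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param rate_hz Sampling rate of the uniform grid in Hz.
#' @return Filtered trace tibble.
#' @export
lowpass_filter <- function(trace, cutoff_hz, rate_hz) {
  stopifnot(cutoff_hz > 0, cutoff_hz < rate_hz / 2)
  bf <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
  for (col in intersect(c("ax", "ay", "az"), names(trace))) {
    trace[[col]] <- as.numeric(signal::filtfilt(bf, trace[[col]]))
  }
  trace
}

#' Euclidean magnitude of the 3-axis acceleration
#'
#' The scalar series the motion-onset threshold is applied to. Using the norm
#' of gravity-free acceleration makes onset detection invariant to how the
#' participant happens to hold the phone (any fixed rotation of the device
#' frame).
#'
#' @param trace Gravity-free trace tibble.
#' @return Non-negative numeric vector, one value per sample, in m/s^2.
#' @export
acc_magnitude <- function(trace) {
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}

#' Full signal preparation for one trial
#'
#' Baseline estimation over the pre-stimulus rest window, gravity removal
#' (skipped for linear-accelerometer devices), resampling onto a uniform
#' grid, and optional zero-phase low-pass filtering.
#'
#' @inheritParams estimate_rest_baseline
#' @param has_linear_accelerometer If `TRUE` the device already removed
#'   gravity and baseline subtraction is skipped.
#' @return Uniform-grid, gravity-free (filtered) trace tibble.
#' @export
prepare_trace <- function(trace, stim_onset, cfg = prep_config(),
                          has_linear_accelerometer = FALSE) {
  if (!has_linear_accelerometer) {
    baseline <- estimate_rest_baseline(trace, stim_onset, cfg)
    trace <- remove_gravity(trace, baseline)
  }
  trace <- resample_uniform(trace, cfg$resample_rate_hz)
  if (!is.null(cfg$lowpass_hz)) {
    trace <- lowpass_filter(trace, cfg$lowpass_hz, cfg$resample_rate_hz)
  }
  trace
}
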