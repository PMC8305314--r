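#' Motion-onset threshold
#'
#' The adaptive threshold of the mAAT processing convention:
#' `max(0.8, 0.3 * a_max)` m/s^2, where `a_max` is the maximum acceleration
#' magnitude observed in the trial's response window. The 0.8 m/s^2 floor
#' keeps sensor noise from triggering onsets on weak movements; the 30%
#' fraction adapts the threshold to vigorous movements.
#'
#' @param a_max Maximum acceleration magnitude in the response window, m/s^2.
#' @return Threshold in m/s^2 (vectorised over `a_max`).
#' @export
#' @examples
#' onset_threshold(10)    # 3.0
#' onset_threshold(1)     # 0.8 (floor)
#' onset_threshold(8 / 3) # 0.8 (branch point)
onset_threshold <- function(a_max) {
  if (any(a_max < 0)) {
    abort("a_max must be non-negative", class = "maatkit_domain_error")
  }
  pmax(0.8, 0.3 * a_max)
}

#' Detect motion onset in an acceleration-magnitude series
#'
#' `a_max` is taken over the response window `(stim_onset, stim_onset +
#' window]` of the current trial only, so the threshold adapts per response.
#' The onset is the time of the first sample strictly exceeding
#' `max(0.8, 0.3 * a_max)`; first-sample-strictly-above is a deterministic
#' tie-break. If no sample exceeds the threshold the trial is a
#' `no_reaction`; an empty or degenerate window is a `no_onset`.
#'
#' @param t Time stamps in seconds (uniform grid).
#' @param mag Acceleration-magnitude series from [acc_magnitude()].
#' @param stim_onset Stimulus onset, seconds on the trace clock.
#' @param window Response window length in seconds (2 s: the stimulus is
#'   removed and the trial scored as no reaction after 2 s).
#' @return A list of class `onset_result` with `onset_time` (seconds or `NA`),
#'   `threshold_used`, `a_max`, `status` (`"responded"`, `"no_reaction"` or
#'   `"no_onset"`) and `truncated` (`TRUE` when the trace ends before the
#'   full window).
#' @export
detect_onset <- function(t, mag, stim_onset, window = 2.0) {
  stopifnot(length(t) == length(mag))
  in_win <- t > stim_onset & t <= stim_onset + window
  if (!any(in_win)) {
    return(structure(list(onset_time = NA_real_, threshold_used = NA_real_,
                          a_max = NA_real_, status = "no_onset",
                          truncated = TRUE),
                     class = "onset_result"))
  }
  truncated <- max(t) < stim_onset + window - 1e-9
  a_max <- max(mag[in_win])
  thr <- onset_threshold(a_max)
  above <- in_win & mag > thr
  if (!any(above)) {
    return(structure(list(onset_time = NA_real_, threshold_used = thr,
                          a_max = a_max, status = "no_reaction",
                          truncated = truncated),
                     class = "onset_result"))
  }
  structure(list(onset_time = t[which(above)[1L]], threshold_used = thr,
                 a_max = a_max, status = "responded", truncated = truncated),
            class = "onset_result")
}

#' Reaction time from a detected onset
#'
#' The time between stimulus onset and onset of the phone's motion, in
#' milliseconds. No validity filtering happens here; the RT validity window
#' is applied by [classify_trial()].
#'
#' @param onset An `onset_result` from [detect_onset()].
#' @param stim_onset Stimulus onset in seconds.
#' @return RT in ms, or `NA` when no onset was detected.
#' @export
reaction_time <- function(onset, stim_onset) {
  if (is.na(onset$onset_time)) return(NA_real_)
  if (onset$onset_time <= stim_onset) {
    abort("detected onset at or before stimulus onset: segmentation bug",
          class = "maatkit_contract_error")
  }
  (onset$onset_time - stim_onset) * 1000
}

#' Extract the outward movement segment
#'
#' Participants push or pull the phone and then immediately return it to the
#' starting position, so the displacement over the whole trial is close to
#' zero by design. The movement distance must therefore be measured over the
#' outward stroke only. The segment runs from the detected onset to the first
#' time after the movement-axis velocity peak at which that velocity crosses
#' zero (the end of the outward phase), capped at `cap_s` after onset.
#'
#' @param trace Uniform-grid, gravity-free trace tibble.
#' @param onset_time Detected onset in seconds.
#' @param cap_s Maximum segment length in seconds.
#' @return A list of class `movement_segment` with `t_start`, `t_end`,
#'   `peak_acc` (max magnitude inside the segment) and flags `capped`
#'   (no zero crossing before the cap) and `degenerate` (fewer than 3
#'   samples available after onset).
#' @export
extract_segment <- function(trace, onset_time, cap_s = 1.0) {
  stopifnot(!is.na(onset_time))
  i0 <- which(trace$t >= onset_time - 1e-9)[1L]
  if (is.na(i0)) {
    abort("onset time beyond trace end", class = "maatkit_contract_error")
  }
  i_cap <- max(which(trace$t <= onset_time + cap_s + 1e-9))
  idx <- i0:i_cap
  if (length(idx) < 3L) {
    return(structure(list(t_start = onset_time, t_end = trace$t[i_cap],
                          peak_acc = max(acc_magnitude(trace[idx, , drop = FALSE])),
                          capped = FALSE, degenerate = TRUE),
                     class = "movement_segment"))
  }
  tt <- trace$t[idx]
  az <- trace$az[idx]
  vz <- pracma::cumtrapz(tt, az)[, 1L]  # v = 0 at onset: phone at rest
  # outward direction = sign of the first substantial velocity excursion;
  # the global |v| maximum could sit on the return stroke instead
  i_sub <- which(abs(vz) >= 0.25 * max(abs(vz)))[1L]
  out_sign <- sign(vz[i_sub])
  if (is.na(out_sign) || out_sign == 0) out_sign <- 1
  s <- vz * out_sign            # outward-positive velocity
  i_peak <- which.max(s)
  after <- seq_along(vz) > i_peak
  crossing <- after & (s <= 0)
  if (any(crossing)) {
    i_end <- which(crossing)[1L]
    capped <- FALSE
  } else {
    i_end <- length(idx)
    capped <- TRUE
  }
  seg_idx <- idx[1L:i_end]
  structure(list(t_start = onset_time, t_end = tt[i_end],
                 peak_acc = max(acc_magnitude(trace[seg_idx, , drop = FALSE])),
                 capped = capped, degenerate = FALSE),
            class = "movement_segment")
}

check_uniform <- function(t) {
  dt <- diff(t)
  if (length(dt) == 0L || any(abs(dt - dt[1L]) > 1e-6 * dt[1L])) {
    abort("trace is not on a uniform grid; run resample_uniform() first",
          class = "maatkit_signal_error")
  }
  dt[1L]
}

#' Movement distance by double integration
#'
#' The mAAT distance: how far the phone travelled during the outward stroke,
#' derived from the magnitude and duration of the acceleration. Velocity is
#' the cumulative trapezoidal integral of the movement-axis (z) acceleration
#' from the segment start, with velocity defined as zero at onset (the phone
#' is at rest between trials); distance is the absolute cumulative integral
#' of that velocity evaluated at the segment end. Sub-second integration over
#' the outward stroke only keeps accelerometer drift second-order.
#'
#' @param trace Uniform-grid, gravity-free trace tibble.
#' @param segment A `movement_segment` from [extract_segment()].
#' @return Distance in meters (non-negative).
#' @export
compute_distance <- function(trace, segment) {
  idx <- which(trace$t >= segment$t_start - 1e-9 &
                 trace$t <= segment$t_end + 1e-9)
  if (length(idx) < 2L) return(0)
  check_uniform(trace$t[idx])
  tt <- trace$t[idx]
  vz <- pracma::cumtrapz(tt, trace$az[idx])[, 1L]
  xz <- pracma::cumtrapz(tt, vz)[, 1L]
  abs(xz[length(xz)])
}

#' Classify the observed movement direction
#'
#' Under the `+z_toward_face` axis convention a pull (approach) movement has
#' positive net z displacement over the outward segment and a push
#' (avoidance) movement negative. Displacements smaller than `min_disp_m`
#' in absolute value are `undetermined` (e.g. purely lateral movements).
#'
#' @inheritParams compute_distance
#' @param min_disp_m Minimum |net z displacement| in meters to call a
#'   direction.
#' @return `"pull"`, `"push"` or `"undetermined"`.
#' @export
classify_direction <- function(trace, segment, min_disp_m = 0.01) {
  idx <- which(trace$t >= segment$t_start - 1e-9 &
                 trace$t <= segment$t_end + 1e-9)
  if (length(idx) < 2L) return("undetermined")
  tt <- trace$t[idx]
  vz <- pracma::cumtrapz(tt, trace$az[idx])[, 1L]
  xz <- pracma::cumtrapz(tt, vz)[, 1L]
  net <- xz[length(xz)]
  if (abs(net) <= min_disp_m) "undetermined" else if (net > 0) "pull" else "push"
}
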