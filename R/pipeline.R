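#' Process one session: raw traces to per-trial metrics
#'
#' Runs the full per-trial chain for every trial in a session: signal
#' preparation ([prepare_trace()]), onset detection ([detect_onset()]),
#' reaction time, outward-segment extraction, distance by double integration
#' and observed-direction classification.
#'
#' The returned `status` is pre-QC: `"valid"` for any detected onset,
#' `"no_reaction"` when no sample exceeded the onset threshold within the
#' response window, `"no_onset"` when the trial could not be processed at all
#' (unusable rest window, empty response window, degenerate trace). Apply the
#' RT validity window with [apply_qc()].
#'
#' @param session A [maat_session()].
#' @param prep A [prep_config()].
#' @param window_s Response window in seconds (default 2).
#' @param segment_cap_s Outward-segment cap in seconds (default 1).
#' @param undetermined_m Direction-call floor in meters (default 0.01).
#' @return A tibble with one row per trial: `participant_id`, `trial`, `block`,
#'   `stimulus_id`, `category`, `instructed_direction`, `rt_ms`,
#'   `distance_m`, `peak_acc_ms2`, `observed_direction`, `status`,
#'   `direction_match`.
#' @export
#' @examples
#' sess <- simulate_experiment(experiment_sim_config(
#'   n_participants = 1, trials_per_cell = 1, seed = 7))$sessions[[1]]
#' process_session(sess)
process_session <- function(session, prep = prep_config(), window_s = 2.0,
                            segment_cap_s = 1.0, undetermined_m = 0.01) {
  stopifnot(inherits(session, "maat_session"))
  trials <- session$trials
  rows <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    row <- trials[i, ]
    base <- tibble::tibble(
      participant_id = session$participant_id,
      trial = i,
      block = row$block,
      stimulus_id = row$stimulus_id,
      category = row$category,
      instructed_direction = row$instructed_direction,
      rt_ms = NA_real_, distance_m = NA_real_, peak_acc_ms2 = NA_real_,
      observed_direction = "undetermined", status = "no_onset",
      direction_match = NA
    )
    prepped <- tryCatch(
      prepare_trace(row$trace[[1L]], row$stim_onset, prep,
                    has_linear_accelerometer = row$has_linear_accelerometer),
      error = function(e) NULL
    )
    if (is.null(prepped)) return(base)
    mag <- acc_magnitude(prepped)
    onset <- detect_onset(prepped$t, mag, row$stim_onset, window = window_s)
    base$peak_acc_ms2 <- onset$a_max
    if (onset$status != "responded") {
      base$status <- onset$status
      return(base)
    }
    base$rt_ms <- reaction_time(onset, row$stim_onset)
    seg <- extract_segment(prepped, onset$onset_time, cap_s = segment_cap_s)
    base$distance_m <- compute_distance(prepped, seg)
    base$observed_direction <-
      classify_direction(prepped, seg, min_disp_m = undetermined_m)
    base$direction_match <-
      base$observed_direction == base$instructed_direction
    base$status <- "valid"
    base
  })
  rows
}

#' Process many sessions into one metrics table
#'
#' @param sessions List of [maat_session()] objects.
#' @inheritParams process_session
#' @return Row-bound metrics tibble (see [process_session()]).
#' @export
process_sessions <- function(sessions, prep = prep_config(), window_s = 2.0,
                             segment_cap_s = 1.0, undetermined_m = 0.01) {
  purrr::map_dfr(sessions, process_session, prep = prep, window_s = window_s,
                 segment_cap_s = segment_cap_s,
                 undetermined_m = undetermined_m)
}
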