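#' Quality-control configuration
#'
#' The published validity rules: reaction times below 200 ms are discarded
#' (anticipations; `too_fast`), reaction times above 2000 ms count as no
#' reactions, and participants with less than 75% valid trials are excluded
#' as incomplete datasets. A participant with exactly 75% valid trials is
#' included ("less than 75%" excludes).
#'
#' @param rt_min_ms Lower RT validity bound in ms.
#' @param rt_max_ms Upper RT validity bound in ms.
#' @param min_valid_fraction Minimum fraction of valid trials for a
#'   participant to be included.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(rt_min_ms = 200, rt_max_ms = 2000,
                      min_valid_fraction = 0.75) {
  stopifnot(rt_min_ms > 0, rt_min_ms < rt_max_ms,
            min_valid_fraction > 0, min_valid_fraction <= 1)
  structure(list(rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms,
                 min_valid_fraction = min_valid_fraction),
            class = "qc_config")
}

#' Classify trial validity status
#'
#' Vectorised over the rows of a metrics table. Trials already marked
#' `no_reaction` / `no_onset` by the kinematics stage keep that status;
#' responded trials become `too_fast` when RT < `rt_min_ms` (strict),
#' `no_reaction` when RT > `rt_max_ms` (strict), and `valid` otherwise.
#'
#' @param metrics Metrics tibble from [process_session()].
#' @param cfg A [qc_config()].
#' @return Character vector of statuses, one per trial.
#' @export
classify_trial <- function(metrics, cfg = qc_config()) {
  dplyr::case_when(
    metrics$status %in% c("no_reaction", "no_onset") ~ metrics$status,
    is.na(metrics$rt_ms)                             ~ "no_onset",
    metrics$rt_ms < cfg$rt_min_ms                    ~ "too_fast",
    metrics$rt_ms > cfg$rt_max_ms                    ~ "no_reaction",
    TRUE                                             ~ "valid"
  )
}

#' Apply trial-level QC to a metrics table
#'
#' Replaces `status` with the output of [classify_trial()]. `too_fast`
#' trials are discarded whole: they are excluded from both RT and distance
#' aggregation downstream (their measured values stay in the table for
#' audit).
#'
#' @inheritParams classify_trial
#' @return The metrics tibble with final `status`.
#' @export
apply_qc <- function(metrics, cfg = qc_config()) {
  metrics$status <- classify_trial(metrics, cfg)
  metrics
}

#' Participant-level validity accounting
#'
#' Counts trial statuses per participant and applies the inclusion rule:
#' `included = valid_fraction >= min_valid_fraction` (so exactly 75% valid is
#' included under the default).
#'
#' @param metrics QC'd metrics tibble ([apply_qc()]).
#' @param cfg A [qc_config()].
#' @return Tibble with one row per participant: `participant_id`, `n_trials`,
#'   `n_valid`, `n_too_fast`, `n_no_reaction`, `n_no_onset`,
#'   `valid_fraction`, `included`.
#' @export
participant_validity <- function(metrics, cfg = qc_config()) {
  stopifnot(nrow(metrics) > 0L)
  metrics |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_valid = sum(.data$status == "valid"),
      n_too_fast = sum(.data$status == "too_fast"),
      n_no_reaction = sum(.data$status == "no_reaction"),
      n_no_onset = sum(.data$status == "no_onset"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      valid_fraction = .data$n_valid / .data$n_trials,
      included = .data$valid_fraction >= cfg$min_valid_fraction
    )
}

#' Cohort quality-control report
#'
#' Per-participant validity table plus cohort totals mirroring the usual
#' data-loss accounting: how many participants started, how many were
#' excluded by the valid-trial criterion, and trial counts by status.
#'
#' @inheritParams participant_validity
#' @return A list of class `maat_qc_report` with elements `participants`
#'   (see [participant_validity()]) and `cohort` (single-row tibble:
#'   `n_participants`, `n_included`, `n_excluded`, `n_trials`, `n_valid`,
#'   `n_too_fast`, `n_no_reaction`, `n_no_onset`).
#' @export
qc_report <- function(metrics, cfg = qc_config()) {
  participants <- participant_validity(metrics, cfg)
  cohort <- tibble::tibble(
    n_participants = nrow(participants),
    n_included = sum(participants$included),
    n_excluded = sum(!participants$included),
    n_trials = sum(participants$n_trials),
    n_valid = sum(participants$n_valid),
    n_too_fast = sum(participants$n_too_fast),
    n_no_reaction = sum(participants$n_no_reaction),
    n_no_onset = sum(participants$n_no_onset)
  )
  structure(list(participants = participants, cohort = cohort),
            class = "maat_qc_report")
}

#' @export
print.maat_qc_report <- function(x, ...) {
  cat("<maat_qc_report>\n")
  with(x$cohort, cat(sprintf(
    "  participants: %d (%d included, %d excluded by the valid-trial rule)\n",
    n_participants, n_included, n_excluded)))
  with(x$cohort, cat(sprintf(
    "  trials: %d (%d valid, %d too fast, %d no reaction, %d no onset)\n",
    n_trials, n_valid, n_too_fast, n_no_reaction, n_no_onset)))
  invisible(x)
}

#' Drop trials from participants that fail the inclusion rule
#'
#' Convenience filter: keeps only trials belonging to included participants.
#'
#' @inheritParams participant_validity
#' @return Filtered metrics tibble.
#' @export
filter_included <- function(metrics, cfg = qc_config()) {
  pv <- participant_validity(metrics, cfg)
  keep <- pv$participant_id[pv$included]
  dropped <- setdiff(pv$participant_id, keep)
  if (length(dropped) > 0L) {
    inform(paste0("excluding ", length(dropped),
                  " participant(s) with < ",
                  round(100 * cfg$min_valid_fraction), "% valid trials: ",
                  paste(dropped, collapse = ", ")))
  }
  dplyr::filter(metrics, .data$participant_id %in% keep)
}
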