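#' Simulate an experiment and write it to disk
#'
#' Writes one session JSON file per participant plus `ground_truth.csv` and a
#' `run_metadata.json` (package version, seed, config) into `out_dir`.
#' A seed is mandatory so runs are reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg An [experiment_sim_config()] with a non-`NULL` seed.
#' @return Invisibly, a list with `session_paths` and `ground_truth_path`.
#' @export
run_simulate <- function(out_dir, cfg = experiment_sim_config(seed = 1)) {
  stopifnot(inherits(cfg, "experiment_sim_config"))
  if (is.null(cfg$seed)) {
    abort("a seed is required for a reproducible simulation run",
          class = "maatkit_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(cfg, traces = TRUE)
  paths <- vapply(sim$sessions, function(s) {
    p <- file.path(out_dir, paste0("session_", s$participant_id, ".json"))
    write_session(s, p, format = "json")
    p
  }, character(1))
  gt_path <- file.path(out_dir, "ground_truth.csv")
  readr::write_csv(sim$ground_truth, gt_path)
  write_run_metadata(out_dir, cfg, cfg$seed)
  invisible(list(session_paths = paths, ground_truth_path = gt_path))
}

write_run_metadata <- function(out_dir, cfg, seed) {
  meta <- list(
    package = "maatkit",
    version = as.character(utils::packageVersion("maatkit")),
    seed = seed,
    config = cfg[!vapply(cfg, is.null, logical(1))]
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Process session files into metrics and QC outputs
#'
#' Reads every session, runs the trace-to-metrics pipeline and trial QC, and
#' writes `metrics.csv`, `qc_participants.csv`, `qc_cohort.json`, plus
#' `ratings.csv` and `neophobia.csv` extracted from the sessions (for the
#' statistics stage). Unreadable session files are skipped with their errors
#' collected; the remaining files are still processed.
#'
#' @param session_paths Character vector of session file paths.
#' @param out_dir Output directory.
#' @param prep A [prep_config()].
#' @param qc A [qc_config()].
#' @return Invisibly, a list with `metrics` (tibble), `qc` (`maat_qc_report`)
#'   and `failures` (named character vector of error messages per failed
#'   file, empty when all parsed).
#' @export
run_process <- function(session_paths, out_dir, prep = prep_config(),
                        qc = qc_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- character()
  sessions <- list()
  for (p in session_paths) {
    s <- tryCatch(read_session(p), error = function(e) e)
    if (inherits(s, "error")) {
      failures[p] <- conditionMessage(s)
      warn(paste0("failed to read ", p, ": ", conditionMessage(s)))
    } else {
      sessions[[length(sessions) + 1L]] <- s
    }
  }
  if (length(sessions) == 0L) {
    abort("no readable sessions", class = "maatkit_io_error")
  }
  metrics <- process_sessions(sessions, prep = prep) |> apply_qc(qc)
  report <- qc_report(metrics, qc)
  write_metrics_table(metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(report$participants,
                   file.path(out_dir, "qc_participants.csv"))
  jsonlite::write_json(report$cohort, file.path(out_dir, "qc_cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  ratings <- purrr::map_dfr(sessions, function(s) {
    if (is.null(s$ratings)) return(NULL)
    dplyr::mutate(s$ratings, participant_id = s$participant_id, .before = 1L)
  })
  if (nrow(ratings) > 0L) {
    readr::write_csv(ratings, file.path(out_dir, "ratings.csv"))
  }
  neophobia <- tibble::tibble(
    participant_id = vapply(sessions, `[[`, character(1), "participant_id"),
    neophobia_score = vapply(sessions, `[[`, numeric(1), "neophobia_score")
  )
  if (any(!is.na(neophobia$neophobia_score))) {
    readr::write_csv(neophobia, file.path(out_dir, "neophobia.csv"))
  }
  invisible(list(metrics = metrics, qc = report, failures = failures))
}

#' Run the statistical battery on processed outputs
#'
#' Applies the participant-inclusion rule, aggregates cells and scores, runs
#' [maat_stats()], and writes `cells.csv`, `scores.csv`, `stats.csv` and
#' `stats.json` into `out_dir`.
#'
#' @param metrics Metrics tibble or path to a `metrics.csv`.
#' @param out_dir Output directory.
#' @param ratings Optional ratings tibble or CSV path.
#' @param neophobia Optional neophobia tibble or CSV path.
#' @param qc A [qc_config()] (inclusion rule).
#' @return Invisibly, a list with `cells`, `scores`, `stats`.
#' @export
run_stats <- function(metrics, out_dir, ratings = NULL, neophobia = NULL,
                      qc = qc_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(metrics)) metrics <- read_metrics_table(metrics)
  if (is.character(ratings)) {
    ratings <- readr::read_csv(ratings, show_col_types = FALSE)
  }
  if (is.character(neophobia)) {
    neophobia <- readr::read_csv(neophobia, show_col_types = FALSE)
  }
  included <- filter_included(metrics, qc)
  cells <- aggregate_cells(included)
  scores <- dplyr::full_join(rt_score(cells), distance_score(cells),
                             by = c("participant_id", "category"))
  stats_tbl <- maat_stats(included, ratings = ratings, neophobia = neophobia)
  readr::write_csv(cells, file.path(out_dir, "cells.csv"))
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
  jsonlite::write_json(stats_tbl, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(cells = cells, scores = scores, stats = stats_tbl))
}
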