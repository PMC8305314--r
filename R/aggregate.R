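#' Aggregate valid trials into participant x category x direction cells
#'
#' The unit of statistical analysis: an average RT and an average distance
#' per participant, stimulus category and movement direction, computed over
#' valid trials only. Cells with zero valid trials are omitted (with a
#' message), which may later drop that participant from paired tests.
#'
#' @param metrics QC'd metrics tibble ([apply_qc()]); trials from excluded
#'   participants should already have been removed ([filter_included()]).
#' @return Tibble with columns `participant_id`, `category`, `direction`,
#'   `mean_rt_ms`, `mean_distance_m`, `n_valid`.
#' @export
aggregate_cells <- function(metrics) {
  valid <- dplyr::filter(metrics, .data$status == "valid")
  cells <- valid |>
    dplyr::group_by(.data$participant_id, .data$category,
                    direction = .data$instructed_direction) |>
    dplyr::summarise(
      mean_rt_ms = mean(.data$rt_ms),
      mean_distance_m = mean(.data$distance_m),
      n_valid = dplyr::n(),
      .groups = "drop"
    )
  n_possible <- dplyr::n_distinct(metrics$participant_id) *
    dplyr::n_distinct(metrics$category) *
    dplyr::n_distinct(metrics$instructed_direction)
  if (nrow(cells) < n_possible) {
    inform(sprintf("%d cell(s) had no valid trials and were omitted",
                   n_possible - nrow(cells)))
  }
  cells
}

#' Approach-motivation RT score: push minus pull
#'
#' For each participant and image category, the mean push RT minus the mean
#' pull RT in milliseconds. A positive score means pulling was faster than
#' pushing, i.e. approach motivation toward that category. Rows where either
#' direction's cell is missing are omitted with a message.
#'
#' @param cells Cell table from [aggregate_cells()].
#' @return Tibble `participant_id`, `category`, `rt_score_ms`.
#' @export
rt_score <- function(cells) {
  wide <- tidyr::pivot_wider(
    dplyr::select(cells, "participant_id", "category", "direction",
                  "mean_rt_ms"),
    names_from = "direction", values_from = "mean_rt_ms")
  for (d in directions) if (!d %in% names(wide)) wide[[d]] <- NA_real_
  incomplete <- is.na(wide$pull) | is.na(wide$push)
  if (any(incomplete)) {
    inform(sprintf("%d participant x category row(s) missing a direction; omitted",
                   sum(incomplete)))
  }
  wide |>
    dplyr::filter(!is.na(.data$pull), !is.na(.data$push)) |>
    dplyr::transmute(.data$participant_id, .data$category,
                     rt_score_ms = .data$push - .data$pull)
}

#' Movement-amplitude distance score: mean of pull and push
#'
#' For each participant and image category, the mean of the pull and push
#' mean distances in meters. Unlike the RT score this is direction-symmetric:
#' it indexes how vigorously the category is moved regardless of direction,
#' the quantity expected to track stimulus arousal.
#'
#' @inheritParams rt_score
#' @return Tibble `participant_id`, `category`, `distance_score_m`.
#' @export
distance_score <- function(cells) {
  wide <- tidyr::pivot_wider(
    dplyr::select(cells, "participant_id", "category", "direction",
                  "mean_distance_m"),
    names_from = "direction", values_from = "mean_distance_m")
  for (d in directions) if (!d %in% names(wide)) wide[[d]] <- NA_real_
  incomplete <- is.na(wide$pull) | is.na(wide$push)
  if (any(incomplete)) {
    inform(sprintf("%d participant x category row(s) missing a direction; omitted",
                   sum(incomplete)))
  }
  wide |>
    dplyr::filter(!is.na(.data$pull), !is.na(.data$push)) |>
    dplyr::transmute(.data$participant_id, .data$category,
                     distance_score_m = (.data$pull + .data$push) / 2)
}
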