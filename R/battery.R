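#' Run the full mAAT statistical battery
#'
#' Reproduces the standard analysis layer on a QC'd metrics table:
#'
#' * 2x2 repeated-measures ANOVAs (category x direction) on mean RT and mean
#'   distance, once for the palatable/unpalatable pair and once for the
#'   dutch/asian pair;
#' * Wilcoxon signed-rank tests on per-participant mean valence, arousal and
#'   wanting ratings, palatable vs unpalatable and asian vs dutch (when
#'   ratings are supplied);
#' * Pearson correlations of the push-minus-pull RT score with mean valence
#'   and wanting per category, and of the neophobia score with the Asian-food
#'   RT score, valence and wanting (when supplied).
#'
#' All tests are two-sided at alpha = 0.05; no multiplicity correction is
#' applied.
#'
#' @param metrics QC'd metrics tibble (after [apply_qc()] and
#'   [filter_included()]).
#' @param ratings Optional ratings tibble: `participant_id`, `stimulus_id`,
#'   `category`, `valence`, `arousal`, `wanting`.
#' @param neophobia Optional tibble `participant_id`, `neophobia_score`.
#' @return A tidy tibble with one row per test: `measure`, `comparison`,
#'   `effect`, `statistic_name`, `statistic`, `df1`, `df2`, `estimate`,
#'   `p.value`, `n`, `method`.
#' @export
maat_stats <- function(metrics, ratings = NULL, neophobia = NULL) {
  cells <- aggregate_cells(metrics)
  rows <- list()
  add <- function(measure, comparison, effect, statistic_name, statistic,
                  df1, df2, estimate, p, n, method) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      measure = measure, comparison = comparison, effect = effect,
      statistic_name = statistic_name, statistic = statistic,
      df1 = df1, df2 = df2, estimate = estimate, p.value = p, n = n,
      method = method)
  }

  pairs <- list(c("palatable", "unpalatable"), c("dutch", "asian"))
  for (measure in c("rt", "distance")) {
    for (pair in pairs) {
      fit <- tryCatch(rm_anova_2x2(cells, measure, pair),
                      maatkit_stats_error = function(e) {
                        warn(sprintf("skipping %s RM-ANOVA (%s): %s", measure,
                                     paste(pair, collapse = " vs "),
                                     conditionMessage(e)))
                        NULL
                      })
      if (is.null(fit)) next
      for (k in seq_len(nrow(fit$effects))) {
        e <- fit$effects[k, ]
        add(paste0("maat_", measure), paste(pair, collapse = " vs "),
            e$effect, "F", e$statistic, e$df1, e$df2, e$pes, e$p.value,
            fit$n, "rm_anova")
      }
    }
  }

  if (!is.null(ratings) && nrow(ratings) > 0L) {
    part_means <- ratings |>
      dplyr::group_by(.data$participant_id, .data$category) |>
      dplyr::summarise(dplyr::across(c("valence", "arousal", "wanting"), mean),
                       .groups = "drop")
    for (scale in c("valence", "arousal", "wanting")) {
      for (pair in pairs) {
        wide <- part_means |>
          dplyr::filter(.data$category %in% pair) |>
          dplyr::select("participant_id", "category",
                        value = dplyr::all_of(scale)) |>
          tidyr::pivot_wider(names_from = "category", values_from = "value") |>
          dplyr::filter(!is.na(.data[[pair[1]]]), !is.na(.data[[pair[2]]]))
        if (nrow(wide) < 5L) next
        wt <- wilcoxon_signed_rank(wide[[pair[1]]], wide[[pair[2]]])
        add(paste0("rating_", scale), paste(pair, collapse = " vs "),
            "category", "W", wt$statistic, NA_real_, NA_real_, NA_real_,
            wt$p.value, wt$n_used, paste0("wilcoxon_", wt$method))
      }
    }
  } else {
    inform("no ratings supplied; rating tests skipped")
  }

  scores <- rt_score(cells)
  if (!is.null(ratings) && nrow(ratings) > 0L) {
    part_means <- ratings |>
      dplyr::group_by(.data$participant_id, .data$category) |>
      dplyr::summarise(dplyr::across(c("valence", "wanting"), mean),
                       .groups = "drop")
    merged <- dplyr::inner_join(scores, part_means,
                                by = c("participant_id", "category"))
    for (cat in unique(merged$category)) {
      sub <- dplyr::filter(merged, .data$category == cat)
      for (scale in c("valence", "wanting")) {
        ct <- tryCatch(pearson_r(sub$rt_score_ms, sub[[scale]]),
                       maatkit_stats_error = function(e) NULL)
        if (is.null(ct)) next
        add("rt_score", paste0(cat, " ~ ", scale), "correlation", "t",
            ct$statistic, 1, ct$df, ct$estimate, ct$p.value, ct$n, "pearson")
      }
    }
  }

  if (!is.null(neophobia) && nrow(neophobia) > 0L) {
    asian_scores <- dplyr::filter(scores, .data$category == "asian")
    merged <- dplyr::inner_join(asian_scores, neophobia, by = "participant_id")
    ct <- tryCatch(pearson_r(merged$rt_score_ms, merged$neophobia_score),
                   maatkit_stats_error = function(e) NULL,
                   error = function(e) NULL)
    if (!is.null(ct)) {
      add("rt_score", "asian ~ neophobia", "correlation", "t", ct$statistic,
          1, ct$df, ct$estimate, ct$p.value, ct$n, "pearson")
    }
    if (!is.null(ratings) && nrow(ratings) > 0L) {
      asian_means <- ratings |>
        dplyr::filter(.data$category == "asian") |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(valence = mean(.data$valence),
                         wanting = mean(.data$wanting), .groups = "drop") |>
        dplyr::inner_join(neophobia, by = "participant_id")
      for (scale in c("valence", "wanting")) {
        ct <- tryCatch(pearson_r(asian_means[[scale]],
                                 asian_means$neophobia_score),
                       maatkit_stats_error = function(e) NULL,
                       error = function(e) NULL)
        if (is.null(ct)) next
        add(paste0("rating_", scale), "asian ~ neophobia", "correlation", "t",
            ct$statistic, 1, ct$df, ct$estimate, ct$p.value, ct$n, "pearson")
      }
    }
  }

  dplyr::bind_rows(rows)
}
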