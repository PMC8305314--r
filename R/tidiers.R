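#' Tidy a repeated-measures ANOVA fit
#'
#' @param x A `maat_rm_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per effect: `term`, `df1`, `df2`, `statistic`,
#'   `p.value`, `pes` (partial eta squared).
#' @export
tidy.maat_rm_anova <- function(x, ...) {
  dplyr::rename(x$effects, term = "effect")
}

#' Glance at a repeated-measures ANOVA fit
#'
#' @inheritParams tidy.maat_rm_anova
#' @return One-row tibble: `measure`, `comparison`, `n`, `n_dropped`.
#' @export
glance.maat_rm_anova <- function(x, ...) {
  tibble::tibble(measure = x$measure,
                 comparison = paste(x$categories, collapse = " vs "),
                 n = x$n, n_dropped = x$n_dropped)
}

#' Tidy a Wilcoxon signed-rank result
#'
#' @param x A `maat_wilcoxon` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic` (W), `w_plus`, `w_minus`, `p.value`,
#'   `n_used`, `n_zero`, `method`.
#' @export
tidy.maat_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, w_plus = x$w_plus,
                 w_minus = x$w_minus, p.value = x$p.value,
                 n_used = x$n_used, n_zero = x$n_zero, method = x$method)
}

#' Tidy a Pearson correlation result
#'
#' @param x A `maat_pearson` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (r), `r_squared`, `statistic` (t),
#'   `df`, `p.value`, `n`.
#' @export
tidy.maat_pearson <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, r_squared = x$r_squared,
                 statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n = x$n)
}
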