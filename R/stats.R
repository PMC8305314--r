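#' Two-by-two repeated-measures ANOVA on cell means
#'
#' Within-subject ANOVA with two 2-level factors -- stimulus category (a
#' chosen pair, e.g. palatable vs unpalatable) and movement direction (pull
#' vs push) -- on per-participant cell means. With 2-level factors sphericity
#' holds trivially and every effect is tested against its own
#' effect-by-subject interaction with df (1, n - 1). Participants missing any
#' of the four cells are dropped listwise (with a message).
#'
#' Sums of squares are computed directly from the cell-mean decomposition;
#' the interaction F is algebraically the squared paired t statistic on each
#' participant's difference of differences.
#'
#' @param cells Cell table from [aggregate_cells()].
#' @param measure `"rt"` (uses `mean_rt_ms`) or `"distance"`
#'   (`mean_distance_m`).
#' @param categories Length-2 character vector naming the category pair.
#' @return Object of class `maat_rm_anova`: a list with `effects` (tibble:
#'   effect, df1, df2, statistic, p.value, pes -- partial eta squared),
#'   `n` (participants analysed), `n_dropped`, `measure`, `categories`.
#' @export
#' @examples
#' cells <- simulate_experiment(experiment_sim_config(
#'   n_participants = 8, trials_per_cell = 4, seed = 3), traces = FALSE)$metrics |>
#'   apply_qc() |> aggregate_cells()
#' rm_anova_2x2(cells, "rt", c("palatable", "unpalatable"))
rm_anova_2x2 <- function(cells, measure = c("rt", "distance"),
                         categories = c("palatable", "unpalatable")) {
  measure <- match.arg(measure)
  stopifnot(length(categories) == 2L)
  value_col <- if (measure == "rt") "mean_rt_ms" else "mean_distance_m"
  wide <- cells |>
    dplyr::filter(.data$category %in% categories) |>
    dplyr::select("participant_id", "category", "direction",
                  value = dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = c("category", "direction"),
                       values_from = "value")
  cell_names <- as.vector(outer(categories, directions, paste, sep = "_"))
  for (cn in cell_names) if (!cn %in% names(wide)) wide[[cn]] <- NA_real_
  complete <- complete.cases(wide[, cell_names])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    inform(sprintf("dropping %d participant(s) with incomplete 2x2 cells",
                   n_dropped))
  }
  y <- as.matrix(wide[complete, cell_names])  # columns: A1_pull A2_pull A1_push A2_push
  n <- nrow(y)
  if (n < 3L) {
    abort(sprintf("repeated-measures ANOVA needs >= 3 complete participants, got %d", n),
          class = "maatkit_stats_error")
  }
  # factor codes per column: category (A) and direction (B)
  a_lev <- rep(categories, times = 2L)
  b_lev <- rep(directions, each = 2L)
  grand <- mean(y)
  subj <- rowMeans(y)
  mean_a <- vapply(categories, function(l) mean(y[, a_lev == l]), numeric(1))
  mean_b <- vapply(directions, function(l) mean(y[, b_lev == l]), numeric(1))
  # subject-by-level means for the error terms
  subj_a <- vapply(categories, function(l) rowMeans(y[, a_lev == l, drop = FALSE]),
                   numeric(n))
  subj_b <- vapply(directions, function(l) rowMeans(y[, b_lev == l, drop = FALSE]),
                   numeric(n))

  ss_a <- 2 * n * sum((mean_a - grand)^2)
  ss_b <- 2 * n * sum((mean_b - grand)^2)
  ss_as <- 2 * sum((subj_a - outer(subj, rep(1, 2)) -
                      outer(rep(1, n), mean_a) + grand)^2)
  ss_bs <- 2 * sum((subj_b - outer(subj, rep(1, 2)) -
                      outer(rep(1, n), mean_b) + grand)^2)
  cell_eff <- colMeans(y) - mean_a[a_lev] - mean_b[b_lev] + grand
  ss_ab <- n * sum(cell_eff^2)
  ss_total <- sum((y - grand)^2)
  ss_subj <- 4 * sum((subj - grand)^2)
  ss_abs <- max(0, ss_total - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs)

  df2 <- n - 1L
  f_of <- function(ss_eff, ss_err) {
    if (ss_eff <= 0 && ss_err <= 0) return(c(0, 1))
    if (ss_err <= 0) return(c(Inf, 0))
    f <- (ss_eff / 1) / (ss_err / df2)
    c(f, pf(f, 1, df2, lower.tail = FALSE))
  }
  fa <- f_of(ss_a, ss_as); fb <- f_of(ss_b, ss_bs); fab <- f_of(ss_ab, ss_abs)
  pes <- function(ss_eff, ss_err) {
    if (ss_eff + ss_err <= 0) 0 else ss_eff / (ss_eff + ss_err)
  }
  effects <- tibble::tibble(
    effect = c("category", "direction", "category:direction"),
    df1 = 1L, df2 = df2,
    statistic = c(fa[1], fb[1], fab[1]),
    p.value = c(fa[2], fb[2], fab[2]),
    pes = c(pes(ss_a, ss_as), pes(ss_b, ss_bs), pes(ss_ab, ss_abs))
  )
  structure(list(effects = effects, n = n, n_dropped = n_dropped,
                 measure = measure, categories = categories),
            class = "maat_rm_anova")
}

#' @export
print.maat_rm_anova <- function(x, ...) {
  cat(sprintf("<maat_rm_anova> %s, %s vs %s, n = %d\n",
              x$measure, x$categories[1], x$categories[2], x$n))
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `x - y`. Zero differences are dropped; ties in
#' the absolute differences receive mid-ranks. The reported statistic is
#' `W = min(W+, W-)`. For `n <= exact_limit` pairs (after dropping zeros) the
#' p-value comes from the exact null distribution of `W+` (computed by the
#' shift-algorithm convolution over sign assignments, valid with mid-ranks);
#' above it, from the normal approximation with continuity correction and
#' tie-corrected variance.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return Object of class `maat_wilcoxon`: list with `statistic` (W),
#'   `w_plus`, `w_minus`, `p.value`, `n_used`, `n_zero`, `method`,
#'   `degenerate` (all differences zero).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 1, 6, 8, 10), c(1, 3, 3, 4, 5))
wilcoxon_signed_rank <- function(x, y, exact_limit = 15L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = NA_real_, w_plus = NA_real_,
                          w_minus = NA_real_, p.value = NA_real_,
                          n_used = 0L, n_zero = n_zero, method = "none",
                          degenerate = TRUE),
                     class = "maat_wilcoxon"))
  }
  if (n < 5L) {
    warn("fewer than 5 nonzero differences; test is very low powered")
  }
  r <- rank(abs(d))  # mid-ranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    # exact distribution of W+ over the 2^n equiprobable sign assignments,
    # by convolution on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    max2 <- sum(r2)
    dist <- numeric(max2 + 1L)  # index k+1 <-> doubled statistic k
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(max2 + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    wp2 <- as.integer(round(2 * w_plus))
    p_le <- sum(dist[seq_len(wp2 + 1L)])
    p_ge <- sum(dist[(wp2 + 1L):(max2 + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = w, w_plus = w_plus, w_minus = w_minus,
                 p.value = p, n_used = n, n_zero = n_zero, method = method,
                 degenerate = FALSE),
            class = "maat_wilcoxon")
}

#' @export
print.maat_wilcoxon <- function(x, ...) {
  cat(sprintf("<maat_wilcoxon> W = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n_used, x$p.value, x$method))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor.test()] reporting r, R^2 and the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both with nonzero
#'   variance.
#' @return Object of class `maat_pearson`: list with `estimate` (r),
#'   `r_squared`, `statistic` (t), `df`, `p.value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    abort("Pearson correlation needs at least 3 complete pairs",
          class = "maatkit_stats_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson correlation undefined for zero-variance input",
          class = "maatkit_stats_error")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  structure(list(estimate = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p.value = ct$p.value,
                 n = length(x)),
            class = "maat_pearson")
}

#' @export
print.maat_pearson <- function(x, ...) {
  cat(sprintf("<maat_pearson> r = %.3f (R^2 = %.3f), n = %d, p = %.4g\n",
              x$estimate, x$r_squared, x$n, x$p.value))
  invisible(x)
}
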