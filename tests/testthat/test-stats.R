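make_cells <- function(n, seed = 1, means = NULL) {
  # complete 2x2 cell table for n participants, palatable/unpalatable pair
  withr::with_seed(seed, {
    tidyr::expand_grid(participant_id = sprintf("p%02d", 1:n),
                       category = c("palatable", "unpalatable"),
                       direction = c("pull", "push")) |>
      dplyr::mutate(
        mean_rt_ms = if (is.null(means)) rnorm(dplyr::n(), 650, 60)
                     else rep_len(means, dplyr::n()),
        mean_distance_m = rnorm(dplyr::n(), 0.25, 0.03),
        n_valid = 10L)
  })
}

test_that("cell aggregation averages valid trials only and logs empty cells", {
  m <- dplyr::bind_rows(
    metrics_row("p1", rt_ms = 400, distance_m = 0.2, trial = 1),
    metrics_row("p1", rt_ms = 600, distance_m = 0.3, trial = 2),
    metrics_row("p1", rt_ms = 150, status = "too_fast", distance_m = 9, trial = 3),
    metrics_row("p1", rt_ms = NA, status = "no_reaction", direction = "push",
                distance_m = NA, trial = 4))
  expect_message(cells <- aggregate_cells(m), "omitted")
  expect_equal(nrow(cells), 1L)  # push cell has no valid trials
  expect_equal(cells$mean_rt_ms, 500)       # too_fast trial fully discarded
  expect_equal(cells$mean_distance_m, 0.25) # its distance is discarded too
  expect_equal(cells$n_valid, 2L)
})

test_that("RT score is push minus pull and distance score the direction mean", {
  cells <- tibble::tibble(
    participant_id = "p1", category = "palatable",
    direction = c("pull", "push"),
    mean_rt_ms = c(650, 700), mean_distance_m = c(0.30, 0.20), n_valid = 5L)
  expect_equal(rt_score(cells)$rt_score_ms, 50)       # approach motivation
  expect_equal(distance_score(cells)$distance_score_m, 0.25)

  equal <- dplyr::mutate(cells, mean_rt_ms = 650, mean_distance_m = 0.25)
  expect_equal(rt_score(equal)$rt_score_ms, 0)
  expect_equal(distance_score(equal)$distance_score_m, 0.25)

  swapped <- dplyr::mutate(cells, mean_rt_ms = rev(mean_rt_ms))
  expect_equal(rt_score(swapped)$rt_score_ms, -50)

  # swapping the direction labels flips rt_score, leaves distance_score
  flipped <- dplyr::mutate(cells,
    direction = ifelse(direction == "pull", "push", "pull"))
  expect_equal(rt_score(flipped)$rt_score_ms, -rt_score(cells)$rt_score_ms)
  expect_equal(distance_score(flipped)$distance_score_m,
               distance_score(cells)$distance_score_m)

  missing <- cells[1, ]
  expect_message(out <- rt_score(missing), "missing a direction")
  expect_equal(nrow(out), 0L)
})

test_that("ANOVA on identical cell means gives F = 0, p = 1", {
  cells <- make_cells(6, means = 500)
  fit <- rm_anova_2x2(cells, "rt")
  expect_equal(fit$effects$statistic, c(0, 0, 0))
  expect_equal(fit$effects$p.value, c(1, 1, 1))
})

test_that("interaction F equals the squared paired t on the difference of differences", {
  for (seed in 1:25) {
    cells <- make_cells(n = sample(4:12, 1), seed = 300 + seed)
    fit <- rm_anova_2x2(cells, "rt")
    wide <- tidyr::pivot_wider(
      dplyr::select(cells, -"mean_distance_m", -"n_valid"),
      names_from = c("category", "direction"), values_from = "mean_rt_ms")
    dod <- (wide$palatable_pull - wide$palatable_push) -
      (wide$unpalatable_pull - wide$unpalatable_push)
    tt <- t.test(dod)
    f_int <- fit$effects$statistic[fit$effects$effect == "category:direction"]
    expect_equal(f_int, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(fit$effects$p.value[fit$effects$effect == "category:direction"],
                 tt$p.value, tolerance = 1e-8)
  }
})

test_that("ANOVA F statistics match the aov() error-stratum oracle", {
  cells <- make_cells(4, seed = 99)
  fit <- rm_anova_2x2(cells, "rt")
  df <- dplyr::mutate(cells,
                      participant_id = factor(participant_id),
                      category = factor(category), direction = factor(direction))
  oracle <- summary(aov(mean_rt_ms ~ category * direction +
                          Error(participant_id / (category * direction)),
                        data = df))
  f_cat <- oracle[["Error: participant_id:category"]][[1]]["category", "F value"]
  f_dir <- oracle[["Error: participant_id:direction"]][[1]]["direction", "F value"]
  f_int <- oracle[["Error: participant_id:category:direction"]][[1]][
    "category:direction", "F value"]
  expect_equal(fit$effects$statistic, unname(c(f_cat, f_dir, f_int)),
               tolerance = 1e-8)
  expect_equal(fit$effects$df2, rep(3L, 3))
})

test_that("ANOVA drops incomplete participants listwise and refuses n < 3", {
  cells <- make_cells(5, seed = 7)
  incomplete <- cells[-2, ]  # p01 loses a cell
  expect_message(fit <- rm_anova_2x2(incomplete, "rt"), "incomplete")
  expect_equal(fit$n, 4)
  expect_equal(fit$n_dropped, 1)

  expect_error(rm_anova_2x2(make_cells(2), "rt"),
               class = "maatkit_stats_error")
})

test_that("within-subject sums of squares reproduce total cell-mean variability", {
  cells <- make_cells(8, seed = 55)
  wide <- tidyr::pivot_wider(
    dplyr::select(cells, -"mean_distance_m", -"n_valid"),
    names_from = c("category", "direction"), values_from = "mean_rt_ms")
  y <- as.matrix(wide[, -1])
  fit <- rm_anova_2x2(cells, "rt")
  # the component SS must sum to the total SS (conservation)
  grand <- mean(y); subj <- rowMeans(y)
  n <- nrow(y)
  # wide columns appear as palatable_pull, palatable_push, unpalatable_pull,
  # unpalatable_push
  a_lev <- rep(c("palatable", "unpalatable"), each = 2)
  b_lev <- rep(c("pull", "push"), times = 2)
  mean_a <- vapply(unique(a_lev), function(l) mean(y[, a_lev == l]), numeric(1))
  mean_b <- vapply(unique(b_lev), function(l) mean(y[, b_lev == l]), numeric(1))
  ss_a <- 2 * n * sum((mean_a - grand)^2)
  ss_b <- 2 * n * sum((mean_b - grand)^2)
  ss_ab <- n * sum((colMeans(y) - mean_a[a_lev] - mean_b[b_lev] + grand)^2)
  ss_subj <- 4 * sum((subj - grand)^2)
  subj_a <- vapply(unique(a_lev),
                   function(l) rowMeans(y[, a_lev == l, drop = FALSE]), numeric(n))
  subj_b <- vapply(unique(b_lev),
                   function(l) rowMeans(y[, b_lev == l, drop = FALSE]), numeric(n))
  ss_as <- 2 * sum((subj_a - subj - rep(mean_a, each = n) + grand)^2)
  ss_bs <- 2 * sum((subj_b - subj - rep(mean_b, each = n) + grand)^2)
  ss_abs <- sum((y - grand)^2) - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs
  expect_equal(ss_a + ss_b + ss_ab + ss_subj + ss_as + ss_bs + ss_abs,
               sum((y - grand)^2), tolerance = 1e-10)
  # and the package's F values are consistent with these components
  expect_equal(fit$effects$statistic,
               c(ss_a / (ss_as / (n - 1)), ss_b / (ss_bs / (n - 1)),
                 ss_ab / (ss_abs / (n - 1))), tolerance = 1e-10)
})

test_that("Wilcoxon signed-rank reproduces hand-computed ranks and exact enumeration", {
  # diffs 1, -2, 3, 4, 5: |d| ranks 1..5, W- = 2
  res <- wilcoxon_signed_rank(c(2, 1, 6, 8, 10), c(1, 3, 3, 4, 5))
  expect_equal(res$statistic, 2)
  expect_equal(res$w_minus, 2)

  # all five diffs positive: W = 0, exact two-sided p = 2/32
  res2 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p.value, 2 / 32)
  expect_equal(res2$method, "exact")
})

test_that("exact Wilcoxon p equals brute-force sign enumeration for n <= 10", {
  withr::with_seed(71, {
    for (n in 5:10) {
      for (rep in 1:3) {
        d <- round(rnorm(n, 0, 3), 1)
        d[d == 0] <- 0.5  # keep n fixed for this check
        res <- wilcoxon_signed_rank(d, rep(0, n))
        expect_equal(res$p.value, brute_wilcoxon_p(d), tolerance = 1e-12)
      }
      # integer data force ties through mid-ranks
      d_ties <- sample(c(-3:-1, 1:3), n, replace = TRUE)
      res_t <- wilcoxon_signed_rank(d_ties, rep(0, n))
      expect_equal(res_t$p.value, brute_wilcoxon_p(d_ties), tolerance = 1e-12)
    }
  })
})

test_that("zero differences are dropped and an all-zero comparison is degenerate", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7), c(1, 1, 1, 2, 2, 2, 7))
  expect_equal(res$n_zero, 2)
  expect_equal(res$n_used, 5)

  res0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p.value))
})

test_that("normal-approximation Wilcoxon p converges to the exact p", {
  withr::with_seed(72, {
    for (rep in 1:5) {
      d <- rnorm(15, 0, 1)
      exact <- wilcoxon_signed_rank(d, rep(0, 15))$p.value
      approx <- wilcoxon_signed_rank(d, rep(0, 15), exact_limit = 0L)$p.value
      expect_lt(abs(approx - exact) / exact, 0.05)
    }
  })
})

test_that("Pearson correlation matches the closed-form r and handles edge inputs", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_r(x, 2 * x + 1)
  expect_equal(res$estimate, 1)
  expect_equal(res$r_squared, 1)

  y_orth <- c(1, -1, 1, -1, 0)  # orthogonal to centred x
  res2 <- pearson_r(x, y_orth)
  expect_equal(res2$estimate, cor(x, y_orth))
  expect_lt(abs(res2$estimate), 0.35)

  # hand table against the direct product-moment formula
  a <- c(2.1, 3.4, 1.2, 5.5, 4.0)
  b <- c(1.0, 2.9, 0.4, 4.1, 4.4)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res3 <- pearson_r(a, b)
  expect_equal(res3$estimate, r_direct, tolerance = 1e-12)
  t_direct <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(res3$p.value, 2 * pt(-abs(t_direct), df = 3), tolerance = 1e-12)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "maatkit_stats_error")
  expect_error(pearson_r(c(1, 2), c(1, 2)), class = "maatkit_stats_error")
})

test_that("statistics are invariant to participant order", {
  cells <- make_cells(9, seed = 12)
  shuffled <- cells[sample(nrow(cells)), ]
  expect_equal(tidy(rm_anova_2x2(cells, "rt")),
               tidy(rm_anova_2x2(shuffled, "rt")))
  s1 <- dplyr::arrange(rt_score(cells), participant_id, category)
  s2 <- dplyr::arrange(rt_score(shuffled), participant_id, category)
  expect_equal(s1, s2)
})

test_that("tidiers return one row per effect or test", {
  fit <- rm_anova_2x2(make_cells(5), "rt")
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_named(td, c("term", "df1", "df2", "statistic", "p.value", "pes"))
  gl <- glance(fit)
  expect_equal(gl$n, 5)
  expect_equal(nrow(tidy(wilcoxon_signed_rank(1:6, c(0, 3, 1, 2, 8, 2)))), 1)
  expect_equal(nrow(tidy(pearson_r(1:5, c(2, 1, 4, 3, 5)))), 1)
})
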