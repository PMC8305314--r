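test_that("simulated strokes hit the analytic min-jerk peak acceleration", {
  cfg <- trace_sim_config(stroke_duration_s = 0.4, displacement_m = 0.25,
                          sample_rate_hz = 200, noise_sd_ms2 = 0,
                          sampling_jitter_sd_s = 0,
                          gravity_vector = c(0, 0, 0),
                          include_return_stroke = FALSE, seed = 1)
  sim <- simulate_trace(cfg)
  peak <- max(abs(sim$trace$az))
  analytic <- (10 / sqrt(3)) * 0.25 / 0.4^2
  expect_equal(peak, analytic, tolerance = 0.02)
  expect_equal(sim$truth$true_peak_acc_ms2, analytic)
})

test_that("a rest-only trace sits at the gravity magnitude", {
  cfg <- trace_sim_config(displacement_m = 0, include_return_stroke = FALSE,
                          noise_sd_ms2 = 0, sampling_jitter_sd_s = 0, seed = 2)
  sim <- simulate_trace(cfg)
  mags <- sqrt(sim$trace$ax^2 + sim$trace$ay^2 + sim$trace$az^2)
  expect_equal(range(mags), c(9.81, 9.81))

  expect_error(trace_sim_config(displacement_m = 0,
                                include_return_stroke = TRUE),
               class = "maatkit_config_error")
})

test_that("the same seed reproduces traces and experiments bit-identically", {
  a <- simulate_trace(trace_sim_config(seed = 33))
  b <- simulate_trace(trace_sim_config(seed = 33))
  expect_identical(a, b)

  cfg <- experiment_sim_config(n_participants = 2, trials_per_cell = 2,
                               seed = 44)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$ground_truth, e2$ground_truth)
  expect_identical(e1$sessions[[1]]$trials$trace[[3]],
                   e2$sessions[[1]]$trials$trace[[3]])
})

test_that("default design yields 4 categories x 2 directions x 20 trials per participant", {
  sim <- simulate_experiment(experiment_sim_config(n_participants = 1, seed = 5),
                             traces = FALSE)
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 160)
  counts <- dplyr::count(gt, category, instructed_direction)
  expect_equal(nrow(counts), 8)
  expect_true(all(counts$n == 20))
})

test_that("emitted sessions satisfy every session invariant", {
  sim <- simulate_experiment(experiment_sim_config(
    n_participants = 2, trials_per_cell = 2, seed = 6))
  for (s in sim$sessions) {
    expect_equal(nrow(validate_session(s)), 0L)
  }
})

test_that("integrating the emitted noiseless acceleration recovers the planted displacement", {
  for (rate in c(100, 200)) {
    cfg <- trace_sim_config(sample_rate_hz = rate, noise_sd_ms2 = 0,
                            sampling_jitter_sd_s = 0,
                            gravity_vector = c(0, 0, 0),
                            include_return_stroke = FALSE, seed = 1)
    sim <- simulate_trace(cfg)
    tr <- sim$trace
    idx <- tr$t >= cfg$true_onset_s - 1e-9
    vz <- pracma::cumtrapz(tr$t[idx], tr$az[idx])[, 1]
    xz <- pracma::cumtrapz(tr$t[idx], vz)[, 1]
    err <- abs(xz[length(xz)] - cfg$displacement_m)
    expect_lt(err, 0.01 * abs(cfg$displacement_m))
    if (rate == 100) err100 <- err else err200 <- err
  }
  expect_gt(err100 / err200, 2.5)  # O(dt^2)
})

test_that("a planted congruency effect is recovered in the RT scores", {
  sim <- simulate_experiment(experiment_sim_config(
    n_participants = 40, congruency_effect_ms = 30, rt_noise_sd_ms = 100,
    seed = 77), traces = FALSE)
  cells <- aggregate_cells(sim$metrics)
  scores <- rt_score(cells)
  pal <- scores$rt_score_ms[scores$category == "palatable"]
  # per-participant score variance: 2 * sd^2 / trials_per_cell
  se <- sqrt(2 * 100^2 / 20 / 40)
  expect_lt(abs(mean(pal) - 30), 3 * se)
  asian <- scores$rt_score_ms[scores$category == "asian"]
  expect_lt(abs(mean(asian) + 30), 3 * se)
})

test_that("with zero effect the planted interaction is null by construction", {
  sim <- simulate_experiment(experiment_sim_config(
    n_participants = 6, congruency_effect_ms = 0, rt_noise_sd_ms = 0,
    seed = 8), traces = FALSE)
  cells <- aggregate_cells(sim$metrics)
  fit <- rm_anova_2x2(cells, "rt")
  expect_equal(fit$effects$statistic[3], 0, tolerance = 1e-12)
})

test_that("recovery_report quantifies bias, RMSE and coverage against ground truth", {
  cfg <- experiment_sim_config(n_participants = 2, trials_per_cell = 2,
                               noise_sd_ms2 = 0, sampling_jitter_sd_s = 0,
                               seed = 9)
  sim <- simulate_experiment(cfg)
  metrics <- process_sessions(sim$sessions) |> apply_qc()
  rep <- recovery_report(sim$ground_truth, metrics)
  expect_equal(rep$quantity, c("rt_ms", "distance_m"))
  # noiseless detection lag is bounded by the analytic threshold-crossing
  # lag of the min-jerk ramp plus one sample
  lag_bound <- (mj_crossing_lag(cfg$stroke_duration_s) + 1 / 100) * 1000
  expect_gt(rep$bias[rep$quantity == "rt_ms"], 0)
  expect_lt(rep$bias[rep$quantity == "rt_ms"], lag_bound + 1e-6)

  bad_truth <- dplyr::mutate(sim$ground_truth,
                             participant_id = paste0("x", participant_id))
  expect_error(recovery_report(bad_truth, metrics),
               class = "maatkit_contract_error")
})

test_that("distance RMSE decreases as sensor noise vanishes", {
  rmse_at <- function(noise) {
    sim <- simulate_experiment(experiment_sim_config(
      n_participants = 1, trials_per_cell = 3, noise_sd_ms2 = noise,
      seed = 10))
    metrics <- process_sessions(sim$sessions) |> apply_qc()
    rep <- recovery_report(sim$ground_truth, metrics)
    rep$rmse[rep$quantity == "distance_m"]
  }
  r <- vapply(c(1.0, 0.3, 0.05), rmse_at, numeric(1))
  expect_true(all(diff(r) < 0))
})
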