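# Shared fixture builders and independent oracles.

# analytic min-jerk kinematics for oracles (independent of minjerk_acc)
mj_pos <- function(t, D, T_s) {
  tau <- pmin(pmax(t / T_s, 0), 1)
  D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}
mj_vel <- function(t, D, T_s) {
  tau <- t / T_s
  v <- (D / T_s) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  v[tau < 0 | tau > 1] <- 0
  v
}
# analytic lag between movement onset and the threshold crossing of a
# min-jerk stroke whose threshold is 0.3 * a_max (root of the cubic)
mj_crossing_lag <- function(T_s) {
  g <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3 - 0.3 * 10 / sqrt(3)
  stats::uniroot(g, c(1e-6, 0.2))$root * T_s
}

# a resting trace (gravity + optional noise), uniform grid
rest_trace <- function(duration = 1, rate = 100, gravity = c(0, 0, -9.81),
                       noise_sd = 0) {
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  tibble::tibble(
    t = t,
    ax = gravity[1] + rnorm(n, 0, noise_sd),
    ay = gravity[2] + rnorm(n, 0, noise_sd),
    az = gravity[3] + rnorm(n, 0, noise_sd)
  )
}

# minimal metrics row builder for QC and stats tests
metrics_row <- function(participant_id = "p1", rt_ms = 500, status = "valid",
                        category = "palatable", direction = "pull",
                        distance_m = 0.2, trial = 1L, block = 1L) {
  tibble::tibble(
    participant_id = participant_id, trial = trial, block = block,
    stimulus_id = "img", category = category,
    instructed_direction = direction, rt_ms = rt_ms,
    distance_m = distance_m, peak_acc_ms2 = 10,
    observed_direction = direction, status = status, direction_match = TRUE
  )
}

# a small simulated session (ratings + traces) for io tests
small_session <- function(seed = 1, trials_per_cell = 1) {
  simulate_experiment(experiment_sim_config(
    n_participants = 1, trials_per_cell = trials_per_cell,
    seed = seed))$sessions[[1]]
}

expect_session_equal <- function(a, b, tolerance = 1e-9) {
  expect_equal(a$participant_id, b$participant_id)
  expect_equal(a$axis_convention, b$axis_convention)
  expect_equal(a$neophobia_score, b$neophobia_score, tolerance = tolerance)
  expect_equal(nrow(a$trials), nrow(b$trials))
  cols <- c("block", "stimulus_id", "category", "instructed_direction",
            "has_linear_accelerometer")
  expect_equal(as.data.frame(a$trials[cols]), as.data.frame(b$trials[cols]))
  expect_equal(a$trials$stim_onset, b$trials$stim_onset, tolerance = tolerance)
  for (i in seq_len(nrow(a$trials))) {
    expect_equal(as.data.frame(a$trials$trace[[i]]),
                 as.data.frame(b$trials$trace[[i]]), tolerance = tolerance)
  }
  if (is.null(a$ratings)) {
    expect_null(b$ratings)
  } else {
    expect_equal(as.data.frame(a$ratings), as.data.frame(b$ratings),
                 tolerance = tolerance)
  }
}

# brute-force exact two-sided Wilcoxon signed-rank p over all 2^n sign
# assignments (independent of the package's convolution implementation)
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
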