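test_that("onset threshold follows max(0.8, 0.3 a_max) with its floor and branch point", {
  expect_equal(onset_threshold(10), 3.0)
  expect_equal(onset_threshold(1.0), 0.8)
  expect_equal(onset_threshold(8 / 3), 0.8)
  expect_error(onset_threshold(-1), class = "maatkit_domain_error")

  a <- seq(0, 30, by = 0.25)
  thr <- onset_threshold(a)
  expect_true(all(thr >= 0.8))
  expect_equal(thr[a >= 8 / 3], 0.3 * a[a >= 8 / 3])
})

test_that("detect_onset finds the first sample strictly above the adaptive threshold", {
  t <- seq(0, 3, by = 0.01)
  mag <- rep(0, length(t))
  mag[t >= 0.9] <- 5  # step at stim_onset + 0.400 with stim at 0.5
  res <- detect_onset(t, mag, stim_onset = 0.5)
  expect_equal(res$status, "responded")
  expect_equal(res$onset_time, 0.9)
  expect_equal(res$threshold_used, 1.5)
  expect_equal(res$a_max, 5)
})

test_that("a series never exceeding the floor is a no-reaction; empty windows are no-onset", {
  t <- seq(0, 3, by = 0.01)
  res <- detect_onset(t, rep(0.5, length(t)), stim_onset = 0.5)
  expect_equal(res$status, "no_reaction")
  expect_true(is.na(res$onset_time))

  res2 <- detect_onset(t, rep(0.5, length(t)), stim_onset = 5)
  expect_equal(res2$status, "no_onset")
})

test_that("reaction time converts onsets to ms without applying validity filtering", {
  mk <- function(ot) structure(list(onset_time = ot), class = "onset_result")
  expect_equal(reaction_time(mk(0.45), 0), 450)
  expect_true(is.na(reaction_time(mk(NA_real_), 0)))
  expect_equal(reaction_time(mk(0.2001), 0), 200.1)
  expect_error(reaction_time(mk(0.4), 0.5), class = "maatkit_contract_error")
})

test_that("segment extraction ends the outward phase at the velocity zero crossing", {
  # constant +2 m/s^2 for 0.5 s then -2 for 0.5 s: v returns to 0 at exactly 1 s
  t <- seq(0, 1.6, by = 0.01)
  az <- ifelse(t < 0.1, 0, ifelse(t < 0.6, 2, ifelse(t < 1.1, -2, 0)))
  az[abs(t - 0.6) < 1e-9] <- 0  # jump midpoint at the sign switch
  tr <- tibble::tibble(t = t, ax = 0, ay = 0, az = az)
  seg <- extract_segment(tr, 0.1)
  expect_equal(seg$t_end, 1.1, tolerance = 1e-9)  # v = 0 reached 1.0 s after onset

  # pure min-jerk outward stroke, no return: v is zero at exactly T
  T_s <- 0.4
  t2 <- seq(0, 1.5, by = 0.005)
  tr2 <- tibble::tibble(t = t2, ax = 0, ay = 0,
                        az = minjerk_acc(t2 - 0.2, 0.25, T_s))
  seg2 <- extract_segment(tr2, 0.2)
  expect_lt(abs(seg2$t_end - (0.2 + T_s)), 0.005 + 1e-9)

  # single-impulse degenerate trace near the end flags as degenerate
  tr3 <- tibble::tibble(t = seq(0, 1, by = 0.01), ax = 0, ay = 0, az = 0)
  seg3 <- extract_segment(tr3, 0.995)
  expect_true(seg3$degenerate)
})

test_that("distance matches closed-form kinematics for a constant-acceleration bang-bang", {
  t <- seq(0, 1.6, by = 0.01)
  az <- ifelse(t < 0.1, 0, ifelse(t < 0.6, 2, ifelse(t < 1.1, -2, 0)))
  az[abs(t - 0.6) < 1e-9] <- 0  # jump midpoint at the sign switch
  tr <- tibble::tibble(t = t, ax = 0, ay = 0, az = az)
  seg <- extract_segment(tr, 0.1)
  # x = 2 * (1/2 * 2 * 0.5^2) = 0.5 m
  expect_equal(compute_distance(tr, seg), 0.5, tolerance = 0.01 * 0.5)

  zero <- tibble::tibble(t = seq(0, 1, 0.01), ax = 0, ay = 0, az = 0)
  seg0 <- structure(list(t_start = 0, t_end = 1), class = "movement_segment")
  expect_equal(compute_distance(zero, seg0), 0)
})

test_that("distance recovers a planted min-jerk displacement and errors on ragged grids", {
  T_s <- 0.4
  t <- seq(0, 1, by = 1 / 200)
  tr <- tibble::tibble(t = t, ax = 0, ay = 0,
                       az = minjerk_acc(t - 0.2, 0.25, T_s))
  seg <- structure(list(t_start = 0.2, t_end = 0.2 + T_s),
                   class = "movement_segment")
  expect_equal(compute_distance(tr, seg), 0.25, tolerance = 0.01 * 0.25)

  ragged <- tr
  ragged$t[100] <- ragged$t[100] + 0.002
  expect_error(compute_distance(ragged, seg), "resample_uniform",
               class = "maatkit_signal_error")
})

test_that("double-integration error scales as O(dt^2)", {
  T_s <- 0.4
  err_at <- function(rate) {
    t <- seq(0, 1, by = 1 / rate)
    tr <- tibble::tibble(t = t, ax = 0, ay = 0,
                         az = minjerk_acc(t - 0.2, 0.25, T_s))
    seg <- structure(list(t_start = 0.2, t_end = 0.2 + T_s),
                     class = "movement_segment")
    abs(compute_distance(tr, seg) - 0.25)
  }
  ratio <- err_at(100) / err_at(200)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
})

test_that("direction classification follows the signed z displacement", {
  mk <- function(D) {
    t <- seq(0, 1.2, by = 0.01)
    tibble::tibble(t = t, ax = 0, ay = 0, az = minjerk_acc(t - 0.2, D, 0.4))
  }
  seg <- structure(list(t_start = 0.2, t_end = 0.6), class = "movement_segment")
  expect_equal(classify_direction(mk(0.25), seg), "pull")
  expect_equal(classify_direction(mk(-0.25), seg), "push")

  lateral <- mk(0.25)
  lateral$ax <- lateral$az
  lateral$az <- 0
  expect_equal(classify_direction(lateral, seg), "undetermined")
})

test_that("detected onset is never earlier than the true onset on noiseless traces", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      latency <- runif(1, 0.2, 0.8)
      cfg <- trace_sim_config(true_onset_s = 0.5 + latency,
                              noise_sd_ms2 = 0, sampling_jitter_sd_s = 0,
                              seed = NULL)
      sim <- simulate_trace(cfg)
      prepped <- prepare_trace(sim$trace, 0.5)
      o <- detect_onset(prepped$t, acc_magnitude(prepped), 0.5)
      expect_gte(o$onset_time, cfg$true_onset_s - 0.01)
    }
  })
})

test_that("distance is invariant to prepending extra rest", {
  cfg <- trace_sim_config(noise_sd_ms2 = 0, sampling_jitter_sd_s = 0, seed = 1)
  sim <- simulate_trace(cfg)
  dist_of <- function(trace, stim) {
    prepped <- prepare_trace(trace, stim)
    o <- detect_onset(prepped$t, acc_magnitude(prepped), stim)
    compute_distance(prepped, extract_segment(prepped, o$onset_time))
  }
  d1 <- dist_of(sim$trace, 0.5)
  shifted <- sim$trace
  pre <- tibble::tibble(t = seq(0, 0.99, by = 0.01),
                        ax = 0, ay = 0, az = -9.81)
  shifted$t <- shifted$t + 1
  longer <- dplyr::bind_rows(pre, shifted)
  d2 <- dist_of(longer, 1.5)
  expect_equal(d1, d2, tolerance = 1e-6)
})
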