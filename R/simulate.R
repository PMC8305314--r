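#' Minimum-jerk acceleration profile
#'
#' Point-to-point human reaching is well described by the minimum-jerk
#' trajectory `x(tau) = D * (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t / T`. Its acceleration is available in closed form, which gives
#' the simulator exact ground truth: peak |acceleration| is
#' `(10 / sqrt(3)) * |D| / T^2` at `tau = (3 - sqrt(3)) / 6`.
#'
#' @param t Times in seconds relative to stroke start (values outside
#'   \[0, T\] give 0).
#' @param D Signed displacement in meters.
#' @param T_s Stroke duration in seconds.
#' @return Acceleration in m/s^2 at each `t`.
#' @export
minjerk_acc <- function(t, D, T_s) {
  tau <- t / T_s
  a <- (D / T_s^2) * (60 * tau - 180 * tau^2 + 120 * tau^3)
  a[tau < 0 | tau > 1] <- 0
  a
}

#' Configuration for a single simulated trial trace
#'
#' Emulates one mAAT trial as recorded by a phone: the participant holds the
#' phone at rest (gravity plus sensor noise), the stimulus appears, and after
#' a latency the phone is moved along the z axis in a minimum-jerk stroke,
#' optionally followed by a mirrored return stroke and a final rest period.
#' Sampling is irregular (Gaussian timestamp jitter, truncated so timestamps
#' stay strictly increasing).
#'
#' @param stim_onset_s Stimulus onset on the trace clock (the preceding rest
#'   mimics the 500 ms fixation period).
#' @param true_onset_s True movement onset (stimulus onset + latency).
#' @param stroke_duration_s Outward stroke duration in seconds.
#' @param displacement_m Signed stroke displacement in meters; positive = pull
#'   (toward the face, +z), negative = push.
#' @param sample_rate_hz Nominal sampling rate.
#' @param sampling_jitter_sd_s Timestamp jitter SD in seconds.
#' @param noise_sd_ms2 Per-axis Gaussian sensor noise SD in m/s^2.
#' @param gravity_vector Gravity in the device frame (m/s^2); the zero vector
#'   emulates a linear accelerometer (gravity removed on-device).
#' @param include_return_stroke Add the mirrored return stroke after a short
#'   pause (participants return the phone immediately, so the full-trial
#'   displacement is near zero by design).
#' @param return_pause_s Pause between outward and return strokes.
#' @param rest_tail_s Rest recorded after the movement.
#' @param seed Optional integer; fixes the whole trace. `NULL` uses the
#'   current RNG stream.
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(stim_onset_s = 0.5, true_onset_s = 0.85,
                             stroke_duration_s = 0.3, displacement_m = 0.25,
                             sample_rate_hz = 100,
                             sampling_jitter_sd_s = 0.001,
                             noise_sd_ms2 = 0.05,
                             gravity_vector = c(0, 0, -9.81),
                             include_return_stroke = TRUE,
                             return_pause_s = 0.15, rest_tail_s = 0.5,
                             seed = NULL) {
  stopifnot(stim_onset_s > 0, true_onset_s > stim_onset_s,
            stroke_duration_s > 0, sample_rate_hz > 0,
            sampling_jitter_sd_s >= 0, noise_sd_ms2 >= 0,
            length(gravity_vector) == 3L)
  if (include_return_stroke && displacement_m == 0) {
    abort("displacement 0 with a return stroke is a degenerate config",
          class = "maatkit_config_error")
  }
  structure(as.list(environment()), class = "trace_sim_config")
}

#' Simulate one trial's sensor trace with ground truth
#'
#' @param cfg A [trace_sim_config()].
#' @return List with `trace` (tibble `t`, `ax`, `ay`, `az`) and `truth`
#'   (one-row tibble: `true_onset_s`, `true_displacement_m`,
#'   `true_direction`, `true_peak_acc_ms2`).
#' @export
#' @examples
#' sim <- simulate_trace(trace_sim_config(seed = 42))
#' sim$truth
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  gen <- function() simulate_trace_impl(cfg)
  if (is.null(cfg$seed)) gen() else withr::with_seed(cfg$seed, gen())
}

simulate_trace_impl <- function(cfg) {
  T_s <- cfg$stroke_duration_s
  move_end <- cfg$true_onset_s + T_s +
    if (cfg$include_return_stroke) cfg$return_pause_s + T_s else 0
  t_end <- max(cfg$stim_onset_s + 2.0, move_end) + cfg$rest_tail_s
  dt <- 1 / cfg$sample_rate_hz
  t <- seq(0, t_end, by = dt)
  if (cfg$sampling_jitter_sd_s > 0) {
    # truncate at 0.4 dt so jittered stamps remain strictly increasing
    j <- rnorm(length(t), 0, cfg$sampling_jitter_sd_s)
    j <- pmax(pmin(j, 0.4 * dt), -0.4 * dt)
    j[1L] <- 0
    t <- t + j
  }
  az <- minjerk_acc(t - cfg$true_onset_s, cfg$displacement_m, T_s)
  if (cfg$include_return_stroke) {
    az <- az + minjerk_acc(t - (cfg$true_onset_s + T_s + cfg$return_pause_s),
                           -cfg$displacement_m, T_s)
  }
  n <- length(t)
  trace <- tibble::tibble(
    t = t,
    ax = cfg$gravity_vector[1L] + rnorm(n, 0, cfg$noise_sd_ms2),
    ay = cfg$gravity_vector[2L] + rnorm(n, 0, cfg$noise_sd_ms2),
    az = cfg$gravity_vector[3L] + az + rnorm(n, 0, cfg$noise_sd_ms2)
  )
  truth <- tibble::tibble(
    true_onset_s = cfg$true_onset_s,
    true_displacement_m = cfg$displacement_m,
    true_direction = if (cfg$displacement_m >= 0) "pull" else "push",
    true_peak_acc_ms2 = (10 / sqrt(3)) * abs(cfg$displacement_m) / T_s^2
  )
  list(trace = trace, truth = truth)
}

# planted explicit-rating profile per category (0-100 scales), encoding the
# expected orderings: valence/wanting palatable > unpalatable and
# dutch > asian; arousal unpalatable > palatable and dutch > asian
planted_ratings <- tibble::tibble(
  category = categories,
  valence = c(75, 20, 70, 55),
  arousal = c(40, 70, 60, 45),
  wanting = c(70, 15, 65, 50)
)

# categories whose natural motivation is approach: pulling them is the
# congruent pairing, pushing incongruent
pull_congruent <- c("palatable", "dutch")

#' Configuration for a simulated mAAT experiment
#'
#' Defaults mirror the study design: 4 stimulus categories x 2 movement
#' directions x 20 trials per cell (10 images per category per experiment
#' half, each presented twice per direction) = 160 experimental trials per
#' participant, in two blocks.
#'
#' Per-trial reaction time is `base_rt_ms` minus half the congruency effect
#' for congruent pairings (pull palatable/dutch, push unpalatable/asian) and
#' plus half for incongruent ones, plus Gaussian noise truncated at 50 ms;
#' the symmetric split keeps marginal direction means equal so main effects
#' and the interaction stay separately testable. Per-trial movement amplitude
#' scales with the planted category arousal:
#' `base_displacement_m * (1 + gain * (arousal - 50) / 50)` times trial-level
#' lognormal noise.
#'
#' @param n_participants Number of participants.
#' @param trials_per_cell Trials per category x direction cell.
#' @param base_rt_ms Mean motion-onset latency in ms.
#' @param congruency_effect_ms Full congruent-vs-incongruent RT difference in
#'   ms (applied as -/+ half).
#' @param rt_noise_sd_ms Trial-level RT noise SD in ms.
#' @param base_displacement_m Baseline stroke amplitude in meters.
#' @param arousal_distance_gain Relative amplitude change per 50 arousal
#'   points above the scale midpoint.
#' @param distance_noise_cv Lognormal coefficient of variation of trial
#'   amplitude.
#' @param stroke_duration_s Outward stroke duration in seconds.
#' @param sample_rate_hz,sampling_jitter_sd_s,noise_sd_ms2,gravity_vector
#'   Sensor model, as in [trace_sim_config()].
#' @param rating_noise_sd Per-image rating noise SD (0-100 scale).
#' @param neophobia_valence_slope Shift of a participant's Asian-food valence
#'   and wanting ratings per neophobia point above 40 (plants the expected
#'   negative neophobia-valence correlation).
#' @param seed Integer seed; fixes the whole experiment.
#' @return A list of class `experiment_sim_config`.
#' @export
experiment_sim_config <- function(n_participants = 20, trials_per_cell = 20,
                                  base_rt_ms = 650,
                                  congruency_effect_ms = 30,
                                  rt_noise_sd_ms = 100,
                                  base_displacement_m = 0.25,
                                  arousal_distance_gain = 0.3,
                                  distance_noise_cv = 0.1,
                                  stroke_duration_s = 0.3,
                                  sample_rate_hz = 100,
                                  sampling_jitter_sd_s = 0.001,
                                  noise_sd_ms2 = 0.05,
                                  gravity_vector = c(0, 0, -9.81),
                                  rating_noise_sd = 8,
                                  neophobia_valence_slope = -0.8,
                                  seed = NULL) {
  stopifnot(n_participants >= 1, trials_per_cell >= 1, base_rt_ms > 0,
            is.finite(congruency_effect_ms), rt_noise_sd_ms >= 0,
            base_displacement_m > 0)
  structure(as.list(environment()), class = "experiment_sim_config")
}

#' Simulate a whole mAAT experiment with known ground truth
#'
#' With `traces = TRUE` (default) every trial gets a full simulated sensor
#' trace and the result is a list of [maat_session()] objects ready for
#' [process_sessions()]. With `traces = FALSE` the planted per-trial metrics
#' are returned directly in the metrics-table shape (the planted-metrics fast
#' path), which is the appropriate input for statistical power and
#' calibration studies where the trace-to-metric layer is not under study.
#'
#' @param cfg An [experiment_sim_config()].
#' @param traces Generate full sensor traces (`TRUE`) or planted metrics only
#'   (`FALSE`).
#' @return A list with `ground_truth` (per-trial tibble) and either
#'   `sessions` (list of sessions; `traces = TRUE`) or `metrics` (tibble in
#'   [process_session()] shape; `traces = FALSE`).
#' @export
#' @examples
#' sim <- simulate_experiment(experiment_sim_config(
#'   n_participants = 2, trials_per_cell = 2, seed = 1), traces = FALSE)
#' head(sim$metrics)
simulate_experiment <- function(cfg, traces = TRUE) {
  stopifnot(inherits(cfg, "experiment_sim_config"))
  gen <- function() simulate_experiment_impl(cfg, traces)
  if (is.null(cfg$seed)) gen() else withr::with_seed(cfg$seed, gen())
}

simulate_experiment_impl <- function(cfg, traces) {
  if (!traces) return(simulate_experiment_fast(cfg))
  n_images <- max(1L, round(cfg$trials_per_cell / 2))
  sessions <- vector("list", cfg$n_participants)
  truth_all <- vector("list", cfg$n_participants)
  metrics_all <- NULL

  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%03d", p)
    design <- tidyr::expand_grid(
      category = categories,
      instructed_direction = directions,
      presentation = seq_len(cfg$trials_per_cell)
    )
    design$stimulus_id <- sprintf("%s_%02d", design$category,
                                  ((design$presentation - 1L) %% n_images) + 1L)
    design$block <- ifelse(design$presentation <= ceiling(cfg$trials_per_cell / 2),
                           1L, 2L)
    # shuffle within block to mimic randomized presentation order
    design <- design[order(design$block, runif(nrow(design))), ]

    congruent <- (design$category %in% pull_congruent) ==
      (design$instructed_direction == "pull")
    rt <- cfg$base_rt_ms +
      ifelse(congruent, -cfg$congruency_effect_ms / 2,
             cfg$congruency_effect_ms / 2) +
      rnorm(nrow(design), 0, cfg$rt_noise_sd_ms)
    rt <- pmax(rt, 50)
    arousal <- planted_ratings$arousal[match(design$category,
                                             planted_ratings$category)]
    amp <- cfg$base_displacement_m *
      (1 + cfg$arousal_distance_gain * (arousal - 50) / 50) *
      exp(rnorm(nrow(design), 0, cfg$distance_noise_cv))
    disp <- ifelse(design$instructed_direction == "pull", amp, -amp)

    truth <- tibble::tibble(
      participant_id = pid,
      trial = seq_len(nrow(design)),
      block = design$block,
      stimulus_id = design$stimulus_id,
      category = design$category,
      instructed_direction = design$instructed_direction,
      congruent = congruent,
      true_rt_ms = rt,
      true_onset_s = 0.5 + rt / 1000,
      true_displacement_m = disp,
      true_direction = design$instructed_direction,
      true_peak_acc_ms2 = (10 / sqrt(3)) * abs(disp) / cfg$stroke_duration_s^2
    )
    truth_all[[p]] <- truth

    neophobia <- min(70, max(10, rnorm(1, 40, 10)))
    ratings <- tidyr::expand_grid(category = categories,
                                  img = seq_len(n_images))
    ratings$stimulus_id <- sprintf("%s_%02d", ratings$category, ratings$img)
    base_r <- planted_ratings[match(ratings$category, planted_ratings$category), ]
    asian_shift <- cfg$neophobia_valence_slope * (neophobia - 40)
    clamp <- function(x) pmin(100, pmax(0, x))
    ratings <- tibble::tibble(
      stimulus_id = ratings$stimulus_id,
      category = ratings$category,
      valence = clamp(base_r$valence +
                        ifelse(ratings$category == "asian", asian_shift, 0) +
                        rnorm(nrow(ratings), 0, cfg$rating_noise_sd)),
      arousal = clamp(base_r$arousal + rnorm(nrow(ratings), 0, cfg$rating_noise_sd)),
      wanting = clamp(base_r$wanting +
                        ifelse(ratings$category == "asian", asian_shift, 0) +
                        rnorm(nrow(ratings), 0, cfg$rating_noise_sd))
    )

    if (traces) {
      trial_traces <- vector("list", nrow(design))
      for (i in seq_len(nrow(design))) {
        tcfg <- trace_sim_config(
          stim_onset_s = 0.5,
          true_onset_s = truth$true_onset_s[i],
          stroke_duration_s = cfg$stroke_duration_s,
          displacement_m = truth$true_displacement_m[i],
          sample_rate_hz = cfg$sample_rate_hz,
          sampling_jitter_sd_s = cfg$sampling_jitter_sd_s,
          noise_sd_ms2 = cfg$noise_sd_ms2,
          gravity_vector = cfg$gravity_vector,
          seed = NULL
        )
        trial_traces[[i]] <- simulate_trace(tcfg)$trace
      }
      trials <- tibble::tibble(
        block = design$block,
        stimulus_id = design$stimulus_id,
        category = design$category,
        instructed_direction = design$instructed_direction,
        stim_onset = 0.5,
        has_linear_accelerometer = all(cfg$gravity_vector == 0),
        trace = trial_traces
      )
      sessions[[p]] <- maat_session(pid, trials, ratings = ratings,
                                    neophobia_score = neophobia)
    }
  }

  list(ground_truth = dplyr::bind_rows(truth_all), sessions = sessions)
}

# planted-metrics fast path: one vectorised pass over all participants
simulate_experiment_fast <- function(cfg) {
  n_images <- max(1L, round(cfg$trials_per_cell / 2))
  pids <- sprintf("p%03d", seq_len(cfg$n_participants))
  design <- tidyr::expand_grid(
    participant_id = pids,
    category = categories,
    instructed_direction = directions,
    presentation = seq_len(cfg$trials_per_cell)
  )
  design$stimulus_id <- sprintf("%s_%02d", design$category,
                                ((design$presentation - 1L) %% n_images) + 1L)
  design$block <- ifelse(design$presentation <= ceiling(cfg$trials_per_cell / 2),
                         1L, 2L)
  design <- design[order(design$participant_id, design$block,
                         runif(nrow(design))), ]
  design$trial <- stats::ave(seq_len(nrow(design)), design$participant_id,
                             FUN = seq_along)

  congruent <- (design$category %in% pull_congruent) ==
    (design$instructed_direction == "pull")
  rt <- pmax(cfg$base_rt_ms +
               ifelse(congruent, -cfg$congruency_effect_ms / 2,
                      cfg$congruency_effect_ms / 2) +
               rnorm(nrow(design), 0, cfg$rt_noise_sd_ms), 50)
  arousal <- planted_ratings$arousal[match(design$category,
                                           planted_ratings$category)]
  amp <- cfg$base_displacement_m *
    (1 + cfg$arousal_distance_gain * (arousal - 50) / 50) *
    exp(rnorm(nrow(design), 0, cfg$distance_noise_cv))
  disp <- ifelse(design$instructed_direction == "pull", amp, -amp)

  ground_truth <- tibble::tibble(
    participant_id = design$participant_id,
    trial = design$trial,
    block = design$block,
    stimulus_id = design$stimulus_id,
    category = design$category,
    instructed_direction = design$instructed_direction,
    congruent = congruent,
    true_rt_ms = rt,
    true_onset_s = 0.5 + rt / 1000,
    true_displacement_m = disp,
    true_direction = design$instructed_direction,
    true_peak_acc_ms2 = (10 / sqrt(3)) * abs(disp) / cfg$stroke_duration_s^2
  )
  metrics <- tibble::tibble(
    participant_id = design$participant_id,
    trial = design$trial,
    block = design$block,
    stimulus_id = design$stimulus_id,
    category = design$category,
    instructed_direction = design$instructed_direction,
    rt_ms = rt,
    distance_m = abs(disp),
    peak_acc_ms2 = ground_truth$true_peak_acc_ms2,
    observed_direction = design$instructed_direction,
    status = "valid",
    direction_match = TRUE
  )

  neophobia_scores <- pmin(70, pmax(10, rnorm(cfg$n_participants, 40, 10)))
  rat <- tidyr::expand_grid(participant_id = pids,
                            category = categories,
                            img = seq_len(n_images))
  base_r <- planted_ratings[match(rat$category, planted_ratings$category), ]
  asian_shift <- ifelse(
    rat$category == "asian",
    cfg$neophobia_valence_slope *
      (neophobia_scores[match(rat$participant_id, pids)] - 40), 0)
  clamp <- function(x) pmin(100, pmax(0, x))
  ratings <- tibble::tibble(
    participant_id = rat$participant_id,
    stimulus_id = sprintf("%s_%02d", rat$category, rat$img),
    category = rat$category,
    valence = clamp(base_r$valence + asian_shift +
                      rnorm(nrow(rat), 0, cfg$rating_noise_sd)),
    arousal = clamp(base_r$arousal + rnorm(nrow(rat), 0, cfg$rating_noise_sd)),
    wanting = clamp(base_r$wanting + asian_shift +
                      rnorm(nrow(rat), 0, cfg$rating_noise_sd))
  )
  list(ground_truth = ground_truth, metrics = metrics, ratings = ratings,
       neophobia = tibble::tibble(participant_id = pids,
                                  neophobia_score = neophobia_scores))
}

#' Ground-truth recovery report
#'
#' Joins simulator ground truth to pipeline outputs by participant and trial
#' and summarises, per recovered quantity, the bias, the RMSE and the
#' fraction of trials within the stated tolerance (RT: +/- 20 ms; distance:
#' +/- 10% relative).
#'
#' @param ground_truth Ground-truth tibble from [simulate_experiment()] (or
#'   row-bound [simulate_trace()] truths with `participant_id`/`trial` added).
#' @param metrics Metrics tibble from [process_sessions()] (must carry the
#'   `trial` column).
#' @return Tibble with one row per quantity: `quantity`, `n`, `bias`, `rmse`,
#'   `coverage` (fraction within tolerance), `tolerance`.
#' @export
recovery_report <- function(ground_truth, metrics) {
  joined <- dplyr::inner_join(ground_truth, metrics,
                              by = c("participant_id", "trial"),
                              suffix = c("_true", ""))
  if (nrow(joined) == 0L) {
    abort("no matching (participant_id, trial) rows between ground truth and metrics",
          class = "maatkit_contract_error")
  }
  ok <- joined$status == "valid" & !is.na(joined$rt_ms)
  rt_err <- joined$rt_ms[ok] - joined$true_rt_ms[ok]
  dist_rel <- (joined$distance_m[ok] - abs(joined$true_displacement_m[ok])) /
    abs(joined$true_displacement_m[ok])
  tibble::tibble(
    quantity = c("rt_ms", "distance_m"),
    n = sum(ok),
    bias = c(mean(rt_err), mean(dist_rel * abs(joined$true_displacement_m[ok]))),
    rmse = c(sqrt(mean(rt_err^2)),
             sqrt(mean((dist_rel * abs(joined$true_displacement_m[ok]))^2))),
    coverage = c(mean(abs(rt_err) <= 20), mean(abs(dist_rel) <= 0.10)),
    tolerance = c("+/- 20 ms", "+/- 10%")
  )
}
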