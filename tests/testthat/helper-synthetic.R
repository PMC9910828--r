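# Shared fixtures for simulation-based tests. Everything is generated in
# code under fixed seeds; no stored data.

seed_mix <- emgreward:::substream_seed

# A single-component contrast config on the In-Out factor structure: the
# a-side (inward perturbation, outward target) carries one evoked response,
# the b-side (inward perturbation, inward target) stays at tonic baseline.
# Only the triceps is simulated, which keeps recovery experiments cheap.
recovery_config <- function(design, latency_ms, amplitude = 3, rho = 1,
                            rise_sd_ms = NULL) {
  comp <- list(selector = list(perturbation = "inward", target = "outward"),
               muscle = "triceps_lat", align = "perturbation",
               latency_ms = latency_ms, amplitude = amplitude)
  if (!is.null(rise_sd_ms)) comp$rise_sd_ms <- rise_sd_ms
  synth_config(design, muscles = "triceps_lat",
               baseline_level = c(triceps_lat = 1),
               reward_gain_factor = rho, participant_latency_sd = 0,
               responses = list(comp))
}

cond_a <- function(reward = "non_rewarded") {
  list(perturbation = "inward", target = "outward", reward = reward)
}
cond_b <- function(reward = "non_rewarded") {
  list(perturbation = "inward", target = "inward", reward = reward)
}

# Processed, perturbation-aligned trials of one condition.
sim_trials <- function(design, condition, config, scalars, n, seed,
                       stream = 1L) {
  lapply(seq_len(n), function(i) {
    tr <- simulate_trial(design, condition, config,
                         seed = seed_mix(seed, stream, i))
    align_trial(preprocess_trial(tr, scalars), "perturbation",
                design$constants$onset_correction_ms)
  })
}

make_scalars <- function(config, seed) {
  normalization_scalar(process_calibration(simulate_calibration(config, seed)))
}

# One participant's estimated reward log-ratio G for a recovery config.
participant_G <- function(design, config, seed, p, n_per_cell,
                          width_ms = 50) {
  sc <- make_scalars(config, seed_mix(seed, 9L, p))
  a_r <- sim_trials(design, cond_a("rewarded"), config, sc, n_per_cell,
                    seed_mix(seed, p), 1L)
  a_n <- sim_trials(design, cond_a("non_rewarded"), config, sc, n_per_cell,
                    seed_mix(seed, p), 2L)
  b_r <- sim_trials(design, cond_b("rewarded"), config, sc, n_per_cell,
                    seed_mix(seed, p), 3L)
  b_n <- sim_trials(design, cond_b("non_rewarded"), config, sc, n_per_cell,
                    seed_mix(seed, p), 4L)
  est_r <- estimate_latency(a_r, b_r, "triceps_lat")
  est_n <- estimate_latency(a_n, b_n, "triceps_lat")
  if (!est_r$valid || !est_n$valid) return(NA_real_)
  win <- c(-100, 300)
  g_r <- feedback_gain(mean_trace(a_r, "triceps_lat", win),
                       mean_trace(b_r, "triceps_lat", win),
                       est_r$latency_ms, width_ms)
  g_n <- feedback_gain(mean_trace(a_n, "triceps_lat", win),
                       mean_trace(b_n, "triceps_lat", win),
                       est_n$latency_ms, width_ms)
  gain_log_ratio(g_r, g_n)
}

# A tiny deterministic trial for unit tests of alignment/baseline/RT logic.
# EMG is set directly (flagged processed); events at stated times.
toy_trial <- function(n = 1200, fs = 1000, emg_value = 1,
                      events = c(target_onset = 200, perturbation = 800,
                                 jump = NA, start_exit = NA,
                                 target_entry = NA),
                      muscles = "triceps_lat") {
  emg <- matrix(emg_value, n, length(muscles),
                dimnames = list(NULL, muscles))
  structure(list(
    trial_id = 1L, participant_id = 1L,
    condition = list(reward = "non_rewarded"),
    fs = fs, time_ms = seq_len(n) - 1, events = events,
    emg = emg, emg_state = "processed",
    kin = cbind(radial_pos = numeric(n), radial_vel = numeric(n)),
    geometry = list(target_distance_cm = 12, target_radius_cm = 3),
    aligned_to = NULL, mt = NA_real_, ground_truth = NULL
  ), class = "trial_recording")
}
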