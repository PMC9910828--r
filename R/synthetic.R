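# Synthetic EMG + kinematics generator with known ground truth.
#
# Raw EMG is modelled as a zero-mean band-limited Gaussian carrier
# amplitude-modulated by a non-negative envelope (tonic baseline + evoked
# responses), so that the package's own conditioning chain (band-pass,
# rectification, normalization) is genuinely exercised: the across-trial
# mean of the processed signal converges to the envelope expressed in
# baseline units.

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the recording setup the designs assume: five muscles
#' sampled at 1000 Hz, tonic pre-activation of the loaded extensors, evoked
#' responses with a half-Gaussian rise (sd 10 ms) to a plateau, log-normal
#' trial-to-trial amplitude jitter, and reward effects expressed as a
#' multiplicative evoked-amplitude factor (the ground-truth `exp(G)`), a
#' movement-time reduction, and a reaction-time reduction.
#'
#' @param design A `task_design`; supplies task-specific defaults.
#' @param n_participants Number of participants; defaults to the design's.
#' @param seed Integer master seed. Every trial, calibration and participant
#'   draws from its own derived stream, so subsets are reproducible.
#' @param fs Sampling rate, Hz.
#' @param muscles Ordered muscle names to simulate.
#' @param baseline_level Named tonic envelope levels (arbitrary raw units;
#'   normalization maps them to 1).
#' @param carrier_band Carrier passband, Hz; must sit inside the analysis
#'   band and below `fs / 2`.
#' @param noise_sd Additive broadband sensor noise (raw units).
#' @param amp_jitter_sd Log-normal sd of per-trial evoked-amplitude jitter.
#' @param participant_amp_sd Log-normal sd of per-participant evoked gain.
#' @param participant_latency_sd Per-participant latency offset sd, ms.
#' @param reward_gain_factor Multiplies evoked amplitudes on rewarded trials
#'   (ground truth `exp(G)`).
#' @param reward_mt_shift_ms Movement-time reduction on rewarded trials, ms.
#' @param reward_rt_shift_ms Reaction-time reduction on rewarded trials, ms
#'   (Proprioception-cued RT task).
#' @param mt_base_ms,mt_noise_sd Mean movement time and its trial sd, ms.
#' @param rt_mean_ms,rt_noise_sd Mean reaction time and its trial sd, ms.
#' @param rise_sd_ms Half-Gaussian rise sd of evoked responses, ms.
#' @param plateau_ms,decay_sd_ms Plateau duration and half-Gaussian decay sd
#'   of evoked responses, ms.
#' @param responses List of evoked-response components; see
#'   [default_responses()].
#' @param max_epochs Optional cap on simulated epochs (reduced-scale runs).
#' @return A `synth_config` object.
#' @export
synth_config <- function(design,
                         n_participants = design$n_participants,
                         seed = 1L,
                         fs = 1000,
                         muscles = c("brachioradialis", "triceps_lat",
                                     "pectoralis", "post_deltoid", "biceps"),
                         baseline_level = c(brachioradialis = 0.4,
                                            triceps_lat = 1.0,
                                            pectoralis = 0.4,
                                            post_deltoid = 0.8,
                                            biceps = 0.3),
                         carrier_band = c(30, 200),
                         noise_sd = 0.05,
                         amp_jitter_sd = 0.2,
                         participant_amp_sd = 0.3,
                         participant_latency_sd = 2,
                         reward_gain_factor = 1.25,
                         reward_mt_shift_ms = 30,
                         reward_rt_shift_ms = 12,
                         mt_base_ms = NULL,
                         mt_noise_sd = 40,
                         rt_mean_ms = 150,
                         rt_noise_sd = 15,
                         rise_sd_ms = 10,
                         plateau_ms = 150,
                         decay_sd_ms = 50,
                         responses = NULL,
                         max_epochs = NULL) {
  if (fs <= 2 * carrier_band[2]) stopf("fs must exceed twice the carrier band")
  if (is.null(mt_base_ms)) {
    mt_base_ms <- switch(design$task_id,
                         in_out = 450, target_selection = 600,
                         cursor_jump = 900, target_jump = 900,
                         proprio_rt = 450)
  }
  cfg <- structure(list(
    task_id = design$task_id, n_participants = n_participants,
    seed = as.integer(seed), fs = fs, muscles = muscles,
    baseline_level = baseline_level[muscles],
    carrier_band = carrier_band, noise_sd = noise_sd,
    amp_jitter_sd = amp_jitter_sd, participant_amp_sd = participant_amp_sd,
    participant_latency_sd = participant_latency_sd,
    reward_gain_factor = reward_gain_factor,
    reward_mt_shift_ms = reward_mt_shift_ms,
    reward_rt_shift_ms = reward_rt_shift_ms,
    mt_base_ms = mt_base_ms, mt_noise_sd = mt_noise_sd,
    rt_mean_ms = rt_mean_ms, rt_noise_sd = rt_noise_sd,
    rise_sd_ms = rise_sd_ms, plateau_ms = plateau_ms,
    decay_sd_ms = decay_sd_ms,
    max_epochs = max_epochs
  ), class = "synth_config")
  cfg$responses <- responses %||% default_responses(design, cfg)
  stopifnot(all(!is.na(cfg$baseline_level)), all(cfg$baseline_level > 0))
  cfg
}

#' Default evoked-response components per task
#'
#' Each component is a list with a condition `selector`, the responding
#' `muscle`, the aligning event (`"perturbation"`, `"jump"`, or `"rt"` for
#' the reaction-time-locked movement burst), an onset `latency_ms` after
#' that event, a signed `amplitude` in baseline units (negative = inhibition
#' of the tonic level), and optionally its own `rise_sd_ms`. The stock sets
#' mirror what each task is built to elicit on the loaded triceps: a
#' short-latency stretch response (25 ms) and goal-dependent long-latency
#' response (50 ms) for the In-Out task, a target-selection response
#' (100 ms), visuomotor jump responses (120 ms), and a sharp
#' reaction-time-locked movement burst for the RT task.
#'
#' @param design A `task_design`.
#' @param config A partially built `synth_config` (for rise defaults).
#' @return List of component lists.
#' @export
default_responses <- function(design, config) {
  tri <- "triceps_lat"
  switch(design$task_id,
    in_out = list(
      # stretch responses are transient bursts; the goal-dependent response
      # is sustained (plateau/decay fall back to the config defaults)
      list(selector = list(perturbation = "inward"), muscle = tri,
           align = "perturbation", latency_ms = 25, amplitude = 3,
           plateau_ms = 25, decay_sd_ms = 20),
      list(selector = list(perturbation = "outward"), muscle = tri,
           align = "perturbation", latency_ms = 25, amplitude = -0.5,
           plateau_ms = 25, decay_sd_ms = 20),
      list(selector = list(perturbation = "inward", target = "outward"),
           muscle = tri, align = "perturbation", latency_ms = 50,
           amplitude = 2.5),
      list(selector = list(perturbation = "inward", target = "inward"),
           muscle = tri, align = "perturbation", latency_ms = 50,
           amplitude = 0.2)
    ),
    target_selection = list(
      list(selector = list(perturbation = "inward", n_targets = "two"),
           muscle = tri, align = "perturbation", latency_ms = 100,
           amplitude = 2.5),
      list(selector = list(perturbation = "inward", n_targets = "one"),
           muscle = tri, align = "perturbation", latency_ms = 100,
           amplitude = -0.4)
    ),
    cursor_jump = ,
    target_jump = list(
      list(selector = list(jump = "inward"), muscle = tri,
           align = "jump", latency_ms = 120, amplitude = 2.5),
      list(selector = list(jump = "outward"), muscle = tri,
           align = "jump", latency_ms = 120, amplitude = -0.5)
    ),
    proprio_rt = list(
      # ballistic movement burst: far above the low tonic pre-activation,
      # with a steep onset
      list(selector = list(), muscle = tri, align = "rt", latency_ms = 0,
           amplitude = 40, rise_sd_ms = 2)
    ),
    stopf("unknown task '%s'", design$task_id)
  )
}

# Minimum-jerk position and velocity profiles on normalized time s in [0,1].
mj_pos <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
mj_vel <- function(s) 30 * s^2 * (1 - s)^2

# Normalized time at which the min-jerk path first enters the target.
mj_entry_s <- function(dist, radius) {
  frac <- (dist - radius) / dist
  stats::uniroot(function(s) mj_pos(s) - frac, c(1e-6, 1),
                 tol = 1e-10)$root
}

# Evoked-response shape: half-Gaussian rise to a plateau, half-Gaussian decay.
response_shape <- function(time_ms, onset, rise_sd, plateau_ms, decay_sd) {
  peak_t <- onset + 3 * rise_sd
  end_t <- peak_t + plateau_ms
  y <- numeric(length(time_ms))
  rising <- time_ms >= onset & time_ms < peak_t
  flat <- time_ms >= peak_t & time_ms < end_t
  falling <- time_ms >= end_t
  y[rising] <- exp(-((time_ms[rising] - peak_t)^2) / (2 * rise_sd^2))
  y[flat] <- 1
  y[falling] <- exp(-((time_ms[falling] - end_t)^2) / (2 * decay_sd^2))
  y
}

# Band-limited Gaussian carrier.
make_carrier <- function(n, config) {
  bandpass(stats::rnorm(n), config$carrier_band[1], config$carrier_band[2],
           config$fs)
}

null_effects <- function() {
  list(amp_factor = 1, mt_shift = 0, rt_shift = 0, latency_shift = 0)
}

#' Simulate a single trial
#'
#' Draws the trial's event times, ground-truth movement/reaction times and
#' evoked amplitudes, builds minimum-jerk radial kinematics and raw
#' multi-channel EMG, and records everything generated in `ground_truth`.
#' Deterministic for a fixed `(design, condition, config, seed)`.
#'
#' @param design A `task_design`.
#' @param condition Named list, one level per design factor.
#' @param config A `synth_config`.
#' @param seed Integer seed for this trial's stream.
#' @param participant_id Participant label stored on the trial.
#' @param effects Per-participant effect list (internal; see
#'   [simulate_dataset()]).
#' @return A `trial_recording` with raw EMG (`emg_state = "raw"`).
#' @export
simulate_trial <- function(design, condition, config, seed,
                           participant_id = 1L, effects = null_effects()) {
  for (f in names(design$factors)) {
    if (is.null(condition[[f]]) || !(condition[[f]] %in% design$factors[[f]])) {
      stopf("condition is missing a valid level for factor '%s'", f)
    }
  }
  rewarded <- identical(condition$reward, "rewarded")
  timing <- design$timing
  geom <- design$geometry
  fs <- config$fs
  visual <- design$mt_definition == "exit_to_target_below_velocity"

  with_seed(seed, {
    events <- c(target_onset = NA_real_, perturbation = NA_real_,
                jump = NA_real_, start_exit = NA_real_,
                target_entry = NA_real_)
    mt_target <- config$mt_base_ms - (if (rewarded) config$reward_mt_shift_ms else 0) +
      effects$mt_shift + stats::rnorm(1, 0, config$mt_noise_sd)
    rt_true <- NA_real_

    if (!visual) {
      events["target_onset"] <- timing$pre_target_ms
      gap <- stats::runif(1, timing$target_to_pert_ms[[1]],
                          timing$target_to_pert_ms[[2]])
      t_pert <- events[["target_onset"]] + gap
      events["perturbation"] <- t_pert
      end_t <- t_pert + timing$post_pert_ms
      mt_target <- min(max(mt_target, 150), timing$post_pert_ms - 50)
      if (design$task_id == "proprio_rt") {
        rt_true <- config$rt_mean_ms -
          (if (rewarded) config$reward_rt_shift_ms else 0) +
          effects$rt_shift + stats::rnorm(1, 0, config$rt_noise_sd)
        rt_true <- min(max(rt_true, 60), mt_target - 100)
        move_start <- t_pert + rt_true
      } else {
        move_start <- t_pert
      }
      s_entry <- mj_entry_s(geom$target_distance_cm, geom$target_radius_cm)
      T_move <- (t_pert + mt_target - move_start) / s_entry
      events["start_exit"] <- move_start
      events["target_entry"] <- t_pert + mt_target
    } else {
      events["target_onset"] <- timing$pre_target_ms +
        stats::runif(1, timing$hold_before_go_ms[[1]],
                     timing$hold_before_go_ms[[2]])
      go_rt <- max(150, stats::rnorm(1, 250, 30))
      move_start <- events[["target_onset"]] + go_rt
      events["start_exit"] <- move_start
      mt_target <- max(mt_target, 400)
      T_move <- solve_visual_duration(mt_target, geom, fs)
      if (!identical(condition$jump, "none")) {
        events["jump"] <- move_start + 0.5 * T_move
      }
      events["target_entry"] <- move_start + mt_target
      end_t <- move_start + T_move + timing$post_entry_ms
    }

    # logged event timestamps live on the sampling grid
    events <- round(events * fs / 1000) * 1000 / fs
    n <- ceiling(end_t)
    time_ms <- seq_len(n) - 1

    # kinematics: radial position (cm) and analytic radial velocity (cm/s)
    s <- pmin(pmax((time_ms - move_start) / T_move, 0), 1)
    pos <- geom$target_distance_cm * mj_pos(s)
    vel <- geom$target_distance_cm * mj_vel(s) / (T_move / 1000)
    kin <- cbind(radial_pos = pos, radial_vel = vel)

    # EMG: envelope per muscle, carrier + sensor noise
    gt_comp <- list()
    emg <- matrix(0, n, length(config$muscles),
                  dimnames = list(NULL, config$muscles))
    for (m in config$muscles) {
      env <- rep(config$baseline_level[[m]], n)
      for (comp in config$responses) {
        if (!identical(comp$muscle, m)) next
        if (!matches_selector(condition, comp$selector)) next
        align_t <- switch(comp$align,
                          perturbation = events[["perturbation"]] +
                            design$constants$onset_correction_ms,
                          jump = events[["jump"]],
                          rt = events[["perturbation"]] +
                            design$constants$onset_correction_ms + rt_true,
                          events[[comp$align]])
        if (is.na(align_t)) next
        lat_shift <- if (identical(comp$align, "rt")) 0 else effects$latency_shift
        onset <- align_t + comp$latency_ms + lat_shift
        amp <- comp$amplitude * effects$amp_factor *
          (if (rewarded) config$reward_gain_factor else 1) *
          exp(stats::rnorm(1, 0, config$amp_jitter_sd))
        rise <- comp$rise_sd_ms %||% config$rise_sd_ms
        env <- env + amp * response_shape(
          time_ms, onset, rise,
          comp$plateau_ms %||% config$plateau_ms,
          comp$decay_sd_ms %||% config$decay_sd_ms)
        gt_comp[[length(gt_comp) + 1]] <- data.frame(
          muscle = m, align = comp$align, onset_ms = onset,
          latency_ms = comp$latency_ms + lat_shift, amplitude = amp)
      }
      env <- pmax(env, 0.02)
      emg[, m] <- env * make_carrier(n, config) +
        config$noise_sd * stats::rnorm(n)
    }

    trial <- structure(list(
      trial_id = NA_integer_, participant_id = participant_id,
      condition = condition, fs = fs, time_ms = time_ms, events = events,
      emg = emg, emg_state = "raw", kin = kin, geometry = geom,
      aligned_to = NULL,
      ground_truth = list(
        mt_target_ms = mt_target, rt_ms = rt_true,
        reward_factor = if (rewarded) config$reward_gain_factor else 1,
        components = if (length(gt_comp)) do.call(rbind, gt_comp) else NULL)
    ), class = "trial_recording")
    trial$mt <- movement_time(trial, design)
    trial$ground_truth$mt_ms <- trial$mt
    trial
  })
}

# Movement duration T (ms) such that the visual movement-time rule (inside
# target AND radial speed < 10 cm/s) is met exactly mt_target ms after
# start exit, for a minimum-jerk path.
solve_visual_duration <- function(mt_target, geom, fs) {
  s_pos <- mj_entry_s(geom$target_distance_cm, geom$target_radius_cm)
  measured <- function(T_move) {
    peak <- 1.875 * geom$target_distance_cm / (T_move / 1000)
    s_vel <- if (peak <= 10) 0 else {
      stats::uniroot(function(s) geom$target_distance_cm * mj_vel(s) /
                       (T_move / 1000) - 10,
                     c(0.5, 1), tol = 1e-9)$root
    }
    T_move * max(s_pos, s_vel)
  }
  stats::uniroot(function(T_move) measured(T_move) - mt_target,
                 c(mt_target, mt_target / s_pos * 1.5), tol = 1e-6)$root
}

#' Simulate the four 2 s calibration holds
#'
#' Stationary envelope at the tonic baseline level, same carrier model as
#' the task trials. Used to compute normalization scalars.
#'
#' @param config A `synth_config`.
#' @param seed Integer seed.
#' @return A `calibration_set` (raw).
#' @export
simulate_calibration <- function(config, seed) {
  n <- 2 * config$fs
  holds <- with_seed(seed, lapply(1:4, function(i) {
    h <- sapply(config$muscles, function(m) {
      config$baseline_level[[m]] * make_carrier(n, config) +
        config$noise_sd * stats::rnorm(n)
    })
    colnames(h) <- config$muscles
    h
  }))
  structure(list(holds = holds, entry_ms = rep(0, 4), fs = config$fs,
                 state = "raw"), class = "calibration_set")
}

#' Simulate a complete multi-participant dataset
#'
#' Generates one trial per schedule row for each participant, plus a
#' calibration set per participant. Per-participant effects (evoked gain,
#' movement-time and reaction-time offsets, latency offset) are drawn from
#' participant-level streams; every trial draws from its own derived stream,
#' so the same master seed always yields a byte-identical dataset and any
#' subset can be regenerated independently.
#'
#' @param design A `task_design`.
#' @param config A `synth_config`.
#' @return An `emg_dataset`: list with `design`, `config`, `schedule`,
#'   `trials` (list of `trial_recording`), `calibrations` (per participant),
#'   and `participants`.
#' @export
simulate_dataset <- function(design, config) {
  schedule <- make_schedule(design, config$seed)
  if (!is.null(config$max_epochs)) {
    schedule <- schedule[schedule$epoch <= config$max_epochs, , drop = FALSE]
  }
  participants <- seq_len(config$n_participants)
  calibrations <- list()
  trials <- vector("list", nrow(schedule) * length(participants))
  k <- 0L
  for (p in participants) {
    eff <- with_seed(substream_seed(config$seed, 1L, p), list(
      amp_factor = exp(stats::rnorm(1, 0, config$participant_amp_sd)),
      mt_shift = stats::rnorm(1, 0, 30),
      rt_shift = stats::rnorm(1, 0, 10),
      latency_shift = stats::rnorm(1, 0, config$participant_latency_sd)
    ))
    calibrations[[as.character(p)]] <-
      simulate_calibration(config, substream_seed(config$seed, 2L, p))
    for (i in seq_len(nrow(schedule))) {
      condition <- as.list(schedule[i, names(design$factors), drop = FALSE])
      condition <- lapply(condition, as.character)
      tr <- simulate_trial(design, condition, config,
                           seed = substream_seed(config$seed, 3L, p, i),
                           participant_id = p, effects = eff)
      tr$trial_id <- schedule$trial_index[i]
      tr$epoch <- schedule$epoch[i]
      tr$block <- schedule$block[i]
      k <- k + 1L
      trials[[k]] <- tr
    }
  }
  structure(list(design = design, config = config, schedule = schedule,
                 trials = trials, calibrations = calibrations,
                 participants = participants),
            class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("emg_dataset: task '%s', %d participants x %d trials, %d muscles (%s)\n",
              x$design$task_id, length(x$participants), nrow(x$schedule),
              length(x$config$muscles),
              if (identical(x$trials[[1]]$emg_state, "processed"))
                "processed" else "raw"))
  invisible(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  cond <- paste(names(x$condition), unlist(x$condition), sep = "=",
                collapse = ", ")
  cat(sprintf("trial_recording %s (participant %s): %s; %d samples @ %g Hz, EMG %s\n",
              x$trial_id, x$participant_id, cond, length(x$time_ms), x$fs,
              x$emg_state))
  invisible(x)
}
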