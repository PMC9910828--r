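#' Load one of the five task designs
#'
#' Reads the structured design library shipped with the package and returns a
#' validated `task_design` object. Each design encodes the task's factor
#' structure, epoch/block composition, analysis contrasts, trial-baseline
#' rule, movement-time definition, monetary-return parameters and hardware
#' constants (background load, perturbation magnitude, sampling rate, and the
#' mechanical perturbation-onset timestamp correction).
#'
#' @param task One of `"in_out"`, `"target_selection"`, `"cursor_jump"`,
#'   `"target_jump"`, `"proprio_rt"`.
#' @param file Optional path to a design YAML file; overrides `task`.
#' @return A `task_design` object (list).
#' @examples
#' d <- task_design("in_out")
#' d$epoch_size * d$n_epochs  # 336 trials
#' @export
task_design <- function(task = c("in_out", "target_selection", "cursor_jump",
                                 "target_jump", "proprio_rt"),
                        file = NULL) {
  if (is.null(file)) {
    task <- match.arg(task)
    file <- system.file("extdata", "designs", paste0(task, ".yaml"),
                        package = "emgreward", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(file)

  rp_list <- lapply(raw$return$conditions, function(cond) {
    sel <- cond$selector %||% list()
    params <- if (identical(raw$return$form, "time_in_target")) {
      return_params(form = "time_in_target", g_max = raw$return$g_max,
                    tau = cond$tau, x0 = raw$return$x0, xf = raw$return$xf)
    } else {
      return_params(form = "movement_time", g_max = raw$return$g_max,
                    tau = cond$tau, scaler = cond$scaler,
                    shifter = cond$shifter, mt_max = cond$mt_max)
    }
    list(selector = sel, params = params)
  })

  design <- structure(list(
    task_id = raw$task_id,
    n_participants = raw$n_participants,
    factors = lapply(raw$factors, as.character),
    copies_per_combo = raw$copies_per_combo,
    epoch_size = raw$epoch_size,
    n_epochs = raw$n_epochs,
    n_blocks = raw$n_blocks,
    baseline_rule = list(event = raw$baseline_event, window_ms = c(-350, -300)),
    mt_definition = raw$mt_definition,
    contrasts = raw$contrasts,
    return_form = raw$return$form,
    return_params = rp_list,
    constants = raw$constants,
    geometry = raw$geometry,
    timing = raw$timing
  ), class = "task_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  n_combo <- prod(lengths(design$factors))
  if (design$epoch_size != design$copies_per_combo * n_combo) {
    stopf("design '%s': epoch_size (%d) != copies_per_combo (%d) x combinations (%d)",
          design$task_id, design$epoch_size, design$copies_per_combo, n_combo)
  }
  total <- design$epoch_size * design$n_epochs
  if (design$n_epochs %% design$n_blocks != 0) {
    stopf("design '%s': %d epochs not divisible into %d blocks",
          design$task_id, design$n_epochs, design$n_blocks)
  }
  for (nm in names(design$contrasts)) {
    ct <- design$contrasts[[nm]]
    if (length(ct$a) == 0 || length(ct$b) == 0) {
      stopf("contrast '%s': empty selector", nm)
    }
    combos <- expand.grid(design$factors, stringsAsFactors = FALSE)
    in_a <- apply(combos, 1, function(r) matches_selector(as.list(r), ct$a))
    in_b <- apply(combos, 1, function(r) matches_selector(as.list(r), ct$b))
    if (!any(in_a) || !any(in_b) || any(in_a & in_b)) {
      stopf("contrast '%s': selectors must be non-empty and disjoint", nm)
    }
  }
  invisible(design)
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Task design '%s': %d trials (%d epochs x %d, %d block%s)\n",
              x$task_id, x$epoch_size * x$n_epochs, x$n_epochs, x$epoch_size,
              x$n_blocks, if (x$n_blocks > 1) "s" else ""))
  cat("  factors: ",
      paste(sprintf("%s{%s}", names(x$factors),
                    vapply(x$factors, paste, "", collapse = ",")),
            collapse = " x "), "\n", sep = "")
  cat("  contrasts:", paste(names(x$contrasts), collapse = ", "), "\n")
  invisible(x)
}

#' Monetary-return parameter set
#'
#' Parameters of the return function paid on rewarded trials. Two forms
#' exist: `time_in_target` (return grows with the time the cursor occupies
#' the target between perturbation onset and trial end) and `movement_time`
#' (return shrinks with movement time).
#'
#' @param form `"time_in_target"` or `"movement_time"`.
#' @param g_max Maximum return in cents; must be positive.
#' @param tau Free calibration parameter (> 0) controlling decay steepness.
#' @param scaler,shifter Dimensionless calibration constants
#'   (movement-time form).
#' @param mt_max Normalizing movement time in ms (movement-time form).
#' @param x0,xf Minimum and maximum time-in-target in ms
#'   (time-in-target form).
#' @return A `return_params` object.
#' @export
return_params <- function(form = c("time_in_target", "movement_time"),
                          g_max, tau, scaler = NULL, shifter = NULL,
                          mt_max = NULL, x0 = NULL, xf = NULL) {
  form <- match.arg(form)
  if (g_max <= 0) stopf("g_max must be > 0")
  if (tau <= 0) stopf("tau must be > 0")
  if (form == "time_in_target") {
    if (is.null(x0) || is.null(xf) || xf <= x0) stopf("need xf > x0")
  } else {
    if (is.null(scaler) || is.null(shifter) || is.null(mt_max) || mt_max <= 0) {
      stopf("movement_time form needs scaler, shifter and mt_max > 0")
    }
  }
  structure(list(form = form, g_max = g_max, tau = tau, scaler = scaler,
                 shifter = shifter, mt_max = mt_max, x0 = x0, xf = xf),
            class = "return_params")
}

# Return-parameter entry matching a trial condition.
lookup_return_params <- function(design, condition) {
  for (entry in design$return_params) {
    if (matches_selector(condition, entry$selector)) return(entry$params)
  }
  stopf("no return parameters match the condition")
}

#' Randomized trial schedule for a task design
#'
#' Builds the full factorial trial list, epoch by epoch, with the trial order
#' shuffled independently within each epoch. Each epoch contains exactly
#' `copies_per_combo` trials of every factor combination. The schedule is a
#' pure function of `(design, seed)`.
#'
#' @param design A `task_design`.
#' @param seed Integer seed; each epoch draws from its own derived stream.
#' @return A data.frame of class `trial_schedule` with columns
#'   `trial_index`, `epoch`, `block` and one column per factor.
#' @examples
#' sched <- make_schedule(task_design("in_out"), seed = 1)
#' nrow(sched)  # 336
#' @export
make_schedule <- function(design, seed) {
  validate_design(design)
  combos <- expand.grid(design$factors, stringsAsFactors = FALSE)
  epoch_rows <- combos[rep(seq_len(nrow(combos)), each = design$copies_per_combo), ,
                       drop = FALSE]
  epochs_per_block <- design$n_epochs / design$n_blocks
  out <- vector("list", design$n_epochs)
  for (e in seq_len(design$n_epochs)) {
    ord <- with_seed(substream_seed(seed, 7L, e),
                     sample.int(nrow(epoch_rows)))
    df <- epoch_rows[ord, , drop = FALSE]
    df$epoch <- e
    df$block <- ceiling(e / epochs_per_block)
    out[[e]] <- df
  }
  sched <- do.call(rbind, out)
  rownames(sched) <- NULL
  sched <- cbind(trial_index = seq_len(nrow(sched)),
                 sched[c("epoch", "block", names(design$factors))])
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Export a trial schedule as CSV
#'
#' @param schedule A `trial_schedule`.
#' @param file Output path.
#' @export
write_schedule <- function(schedule, file) {
  utils::write.csv(as.data.frame(schedule), file, row.names = FALSE)
  invisible(file)
}

#' Monetary return for the In-Out Target task
#'
#' `return = g * exp(-tau * p)` with `p = 1 - min((x - x0)/(xf - x0), 1)`,
#' where `x` is the time (ms) the cursor spent inside the target between
#' perturbation onset and trial end. The return is paid in cents and is
#' non-decreasing in `x`, reaching `g_max` at `x = xf`.
#'
#' @param x Time in target, ms (vectorized).
#' @param params A `return_params` with `form = "time_in_target"`.
#' @return Return in cents.
#' @examples
#' p <- return_params("time_in_target", g_max = 15, tau = 1.428,
#'                    x0 = 500, xf = 800)
#' in_out_return(800, p)  # 15 cents
#' @export
in_out_return <- function(x, params) {
  if (!inherits(params, "return_params") || params$form != "time_in_target") {
    stopf("in_out_return needs return_params with form = 'time_in_target'")
  }
  if (any(x < 0)) stopf("x must be >= 0")
  p <- 1 - pmin((x - params$x0) / (params$xf - params$x0), 1)
  params$g_max * exp(-params$tau * p)
}

#' Monetary return for the movement-time based tasks
#'
#' `return = max(g * (scaler * exp(-tau * p) + shifter), 0)` with
#' `p = MT / MTmax`. Used by the Proprioception-cued Reaction Time, Cursor
#' Jump, Target Jump and Target Selection tasks; non-increasing in `mt`.
#'
#' @param mt Movement time, ms (vectorized).
#' @param params A `return_params` with `form = "movement_time"`.
#' @return Return in cents.
#' @examples
#' p <- return_params("movement_time", g_max = 10, tau = 2.447,
#'                    scaler = 1, shifter = 0, mt_max = 728)
#' mt_return(0, p)  # 10 cents
#' @export
mt_return <- function(mt, params) {
  if (!inherits(params, "return_params") || params$form != "movement_time") {
    stopf("mt_return needs return_params with form = 'movement_time'")
  }
  if (any(mt < 0)) stopf("mt must be >= 0")
  p <- mt / params$mt_max
  pmax(params$g_max * (params$scaler * exp(-params$tau * p) + params$shifter), 0)
}

#' Monetary return for any trial of a task
#'
#' Dispatches on the design's return form: time-in-target (In-Out task,
#' computed from the trial's kinematics) or movement time. Non-rewarded
#' trials always return 0.
#'
#' @param trial A `trial_recording`.
#' @param design The trial's `task_design`.
#' @return Return in cents (0 on non-rewarded or invalid trials).
#' @export
trial_return <- function(trial, design) {
  if (!identical(trial$condition$reward, "rewarded")) return(0)
  params <- lookup_return_params(design, trial$condition)
  if (design$return_form == "time_in_target") {
    in_out_return(time_in_target(trial), params)
  } else {
    mt <- movement_time(trial, design)
    if (is.na(mt)) return(0)
    mt_return(mt, params)
  }
}

#' Accumulated time in target after perturbation onset
#'
#' Counts samples (at the recording rate) for which the cursor is inside the
#' target, from perturbation onset to trial end. Occupancy need not be
#' contiguous.
#'
#' @param trial A `trial_recording` with kinematics and geometry.
#' @return Time in target, ms.
#' @export
time_in_target <- function(trial) {
  t_pert <- trial$events[["perturbation"]]
  if (is.null(t_pert) || is.na(t_pert)) stopf("trial has no perturbation event")
  sel <- trial$time_ms >= t_pert
  inside <- trial$kin[sel, "radial_pos"] >=
    trial$geometry$target_distance_cm - trial$geometry$target_radius_cm
  sum(inside) * 1000 / trial$fs
}

#' Movement time of a trial
#'
#' Applies the design's movement-time definition to the trial kinematics:
#' \describe{
#'   \item{perturbation_to_target_entry}{time from perturbation onset to the
#'     first sample inside the end target, regardless of velocity
#'     (proprioceptive tasks).}
#'   \item{exit_to_target_below_velocity}{time from leaving the start
#'     position to the first sample inside the end target with radial speed
#'     below 10 cm/s (visual tasks). Radial velocity is taken from centered
#'     finite differences of radial position.}
#' }
#'
#' @param trial A `trial_recording`.
#' @param design The trial's `task_design`.
#' @param velocity_criterion_cm_s Speed threshold for the visual definition.
#' @return Movement time in ms, or `NA` if the criterion is never met (the
#'   trial is then flagged invalid downstream).
#' @export
movement_time <- function(trial, design, velocity_criterion_cm_s = 10) {
  pos <- trial$kin[, "radial_pos"]
  entry_dist <- trial$geometry$target_distance_cm - trial$geometry$target_radius_cm
  if (design$mt_definition == "perturbation_to_target_entry") {
    t0 <- trial$events[["perturbation"]]
    if (is.null(t0) || is.na(t0)) stopf("trial has no perturbation event")
    ok <- trial$time_ms >= t0 & pos >= entry_dist
  } else {
    t0 <- trial$events[["start_exit"]]
    if (is.null(t0) || is.na(t0)) stopf("trial has no start_exit event")
    dt_s <- 1 / trial$fs
    # centered finite differences, cm/s
    vel <- c(NA, (pos[-(1:2)] - pos[seq_len(length(pos) - 2)]) / (2 * dt_s), NA)
    ok <- trial$time_ms >= t0 & pos >= entry_dist &
      !is.na(vel) & abs(vel) < velocity_criterion_cm_s
  }
  if (!any(ok)) return(NA_real_)
  trial$time_ms[which(ok)[1]] - t0
}
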