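# EMG conditioning chain: band-pass -> full-wave rectification -> calibration
# normalization, plus event alignment and trial-baseline statistics.

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass (20-250 Hz by default) applied
#' forward-backward so the net filter has zero phase: any group delay would
#' bias every latency estimate downstream. The series mean is removed before
#' filtering (DC lies outside the passband) and the series is extended by
#' odd reflection at both ends before the two passes to suppress edge
#' transients; the first and last ~50 ms should still be treated as
#' transient and kept out of analysis windows.
#'
#' @param x Numeric series sampled at `fs`.
#' @param lo_hz,hi_hz Passband edges in Hz.
#' @param fs Sampling rate, Hz; must exceed `2 * hi_hz`.
#' @param order Butterworth order per passband edge; the band-pass has
#'   `2 * order` poles (the default gives a 4th-order band-pass).
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, lo_hz = 20, hi_hz = 250, fs = 1000, order = 2) {
  if (fs <= 2 * hi_hz) stopf("fs must exceed twice the upper band edge")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  n <- length(x)
  padlen <- min(n - 1L, 3L * max(ceiling(fs / lo_hz), length(bf$b)))
  if (padlen < length(bf$b)) stopf("series too short to filter")
  x0 <- x - mean(x)
  # odd (point-symmetric) reflection, as in standard filtfilt implementations
  head_pad <- 2 * x0[1] - x0[(padlen + 1):2]
  tail_pad <- 2 * x0[n] - x0[(n - 1):(n - padlen)]
  ext <- c(head_pad, x0, tail_pad)
  y <- signal::filter(bf, ext)
  y <- rev(signal::filter(bf, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Full-wave rectification
#'
#' @param x Numeric series.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Per-muscle EMG normalization scalars from calibration holds
#'
#' The four 2 s static holds are trimmed to the window from 250 ms after
#' start-position entry to 250 ms before the end of the 2 s window,
#' concatenated (4 x 1500 ms = 6000 samples at 1000 Hz) and averaged per
#' muscle. Holds must already be band-passed and rectified (see
#' [process_calibration()]).
#'
#' @param cal A `calibration_set` with `state = "processed"`.
#' @return Named numeric vector of positive scalars, one per muscle, of
#'   class `normalization_scalars`.
#' @export
normalization_scalar <- function(cal) {
  if (!inherits(cal, "calibration_set")) stopf("cal must be a calibration_set")
  if (!identical(cal$state, "processed")) {
    stopf("calibration holds must be band-passed and rectified first")
  }
  if (length(cal$holds) != 4L) stopf("calibration requires exactly four holds")
  fs <- cal$fs
  pooled <- lapply(seq_along(cal$holds), function(i) {
    h <- cal$holds[[i]]
    entry <- cal$entry_ms[i]
    if (nrow(h) < (entry / 1000 + 2) * fs) stopf("hold %d shorter than 2 s", i)
    from <- round((entry + 250) * fs / 1000) + 1L
    to <- round((entry + 2000 - 250) * fs / 1000)
    h[from:to, , drop = FALSE]
  })
  pooled <- do.call(rbind, pooled)
  scalars <- colMeans(pooled)
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    stopf("degenerate calibration: non-positive normalization scalar")
  }
  structure(scalars, class = "normalization_scalars")
}

#' Band-pass and rectify calibration holds
#'
#' @param cal A raw `calibration_set`.
#' @param lo_hz,hi_hz Passband edges, Hz.
#' @return The calibration set with processed holds.
#' @export
process_calibration <- function(cal, lo_hz = 20, hi_hz = 250) {
  if (identical(cal$state, "processed")) return(cal)
  cal$holds <- lapply(cal$holds, function(h) {
    apply(h, 2, function(col) rectify(bandpass(col, lo_hz, hi_hz, cal$fs)))
  })
  cal$state <- "processed"
  cal
}

#' Express an EMG series in normalization units
#'
#' @param x Rectified EMG series.
#' @param scalars A `normalization_scalars` vector.
#' @param muscle Muscle name; must be present in `scalars`.
#' @return `x / scalars[muscle]`.
#' @export
normalize_emg <- function(x, scalars, muscle) {
  if (!muscle %in% names(scalars)) stopf("no normalization scalar for '%s'", muscle)
  x / scalars[[muscle]]
}

#' Re-index a trial so an event sits at time zero
#'
#' Shifts the trial's time base so that the (corrected) event time is 0.
#' `onset_correction_ms` compensates the lag between the logged command
#' onset of a mechanical perturbation and the actual limb acceleration
#' (4 ms on this apparatus); it must be 0 for visual events, whose logged
#' timestamps are already photodiode-corrected. Aligning twice to the same
#' event is a no-op.
#'
#' @param trial A `trial_recording`.
#' @param event Name of the event to align to (e.g. `"perturbation"`,
#'   `"jump"`, `"target_onset"`).
#' @param onset_correction_ms Correction added to the logged event time.
#' @return The trial with shifted `time_ms` and event times, and
#'   `aligned_to` set.
#' @export
align_trial <- function(trial, event, onset_correction_ms = 0) {
  t_ev <- trial$events[[event]]
  if (is.null(t_ev) || is.na(t_ev)) stopf("trial has no '%s' event", event)
  shift <- t_ev + onset_correction_ms
  trial$time_ms <- trial$time_ms - shift
  trial$events <- trial$events - shift
  trial$aligned_to <- event
  trial
}

#' Trial-baseline EMG statistics
#'
#' Mean and standard deviation of the processed EMG in the 50 ms window from
#' 350 to 300 ms before the design's baseline event (displacement onset for
#' the mechanical-perturbation tasks; target appearance for the jump tasks,
#' where displacements occur mid-movement). The window is half-open,
#' `[-350, -300)` ms relative to the event.
#'
#' @param trial A processed `trial_recording`.
#' @param design The trial's `task_design`.
#' @return A `baseline_stats` object: matrix with rows `mean` and `sd`, one
#'   column per muscle, plus the window used.
#' @export
trial_baseline <- function(trial, design) {
  ev <- design$baseline_rule$event
  t_ev <- trial$events[[ev]]
  if (is.null(t_ev) || is.na(t_ev)) stopf("trial has no '%s' event", ev)
  win <- t_ev + design$baseline_rule$window_ms
  sel <- trial$time_ms >= win[1] & trial$time_ms < win[2]
  if (sum(sel) < diff(design$baseline_rule$window_ms) * trial$fs / 1000) {
    stopf("insufficient pre-event data for the trial baseline window")
  }
  seg <- trial$emg[sel, , drop = FALSE]
  stats <- rbind(mean = colMeans(seg), sd = apply(seg, 2, stats::sd))
  structure(list(stats = stats, window_ms = win, event = ev),
            class = "baseline_stats")
}

#' Apply the full conditioning chain to one trial
#'
#' Band-pass (20-250 Hz), full-wave rectify, and normalize every muscle
#' channel by its calibration scalar. The order of the chain is fixed.
#'
#' @param trial A raw `trial_recording`.
#' @param scalars `normalization_scalars` for the trial's participant.
#' @param lo_hz,hi_hz Passband edges, Hz.
#' @return The trial with `emg_state = "processed"`.
#' @export
preprocess_trial <- function(trial, scalars, lo_hz = 20, hi_hz = 250) {
  if (identical(trial$emg_state, "processed")) return(trial)
  for (m in colnames(trial$emg)) {
    x <- rectify(bandpass(trial$emg[, m], lo_hz, hi_hz, trial$fs))
    trial$emg[, m] <- normalize_emg(x, scalars, m)
  }
  trial$emg_state <- "processed"
  trial
}

#' Preprocess every trial of a dataset
#'
#' Computes per-participant normalization scalars from the calibration holds
#' and applies [preprocess_trial()] to each trial.
#'
#' @param dataset An `emg_dataset` (see [simulate_dataset()] or
#'   [read_dataset()]).
#' @param lo_hz,hi_hz Passband edges, Hz.
#' @return The dataset with processed trials and a `scalars` element.
#' @export
preprocess_dataset <- function(dataset, lo_hz = 20, hi_hz = 250) {
  scalars <- lapply(dataset$calibrations, function(cal) {
    normalization_scalar(process_calibration(cal, lo_hz, hi_hz))
  })
  dataset$trials <- lapply(dataset$trials, function(tr) {
    preprocess_trial(tr, scalars[[as.character(tr$participant_id)]], lo_hz, hi_hz)
  })
  dataset$scalars <- scalars
  dataset
}
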