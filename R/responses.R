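# Feedback-gain quantification (windowed trapezoid-integral EMG differences
# and reward log-ratios), proprioception-cued reaction-time detection, and
# the anticipatory-EMG control check.

#' Pointwise mean EMG trace across trials
#'
#' @param trials List of processed, aligned `trial_recording`s sharing a
#'   time base.
#' @param muscle Muscle channel.
#' @param window_ms Optional window, ms, relative to the alignment event;
#'   `NULL` keeps the common time span.
#' @return A list with `times` and `mean`.
#' @export
mean_trace <- function(trials, muscle, window_ms = NULL) {
  if (length(trials) == 0) stopf("no trials supplied")
  t0 <- max(vapply(trials, function(tr) min(tr$time_ms), numeric(1)))
  t1 <- min(vapply(trials, function(tr) max(tr$time_ms), numeric(1)))
  if (!is.null(window_ms)) {
    t0 <- max(t0, window_ms[1]); t1 <- min(t1, window_ms[2])
  }
  if (t1 <= t0) stopf("trials share no common window")
  vals <- vapply(trials, function(tr) {
    sel <- tr$time_ms >= t0 & tr$time_ms <= t1
    tr$emg[sel, muscle]
  }, numeric(round(t1 - t0) * trials[[1]]$fs / 1000 + 1))
  list(times = seq(t0, t1, by = 1000 / trials[[1]]$fs),
       mean = rowMeans(as.matrix(vals)))
}

#' Trapezoid integral of a mean trace over a window
#'
#' @param trace A list with `times` (ms) and `mean`, as returned by
#'   [mean_trace()].
#' @param start_ms Window start, ms.
#' @param width_ms Window width, ms.
#' @return Integral in normalized-EMG x ms.
#' @export
trace_integral <- function(trace, start_ms, width_ms) {
  sel <- trace$times >= start_ms & trace$times <= start_ms + width_ms
  if (sum(sel) < 2 || min(trace$times) > start_ms ||
      max(trace$times) < start_ms + width_ms) {
    stopf("integration window [%g, %g] ms exceeds the trace",
          start_ms, start_ms + width_ms)
  }
  pracma::trapz(trace$times[sel], trace$mean[sel])
}

#' Feedback gain: absolute difference of windowed EMG integrals
#'
#' The gain is the absolute difference between the trapezoid-rule integrals
#' of two condition-mean EMG traces over a window anchored at the response
#' latency (width 25 ms for the short-latency stretch-response contrast,
#' 50 ms otherwise). Units: normalized EMG x ms; only ratios of gains are
#' interpreted downstream.
#'
#' @param mean_a,mean_b Condition-mean traces from [mean_trace()].
#' @param start_ms Window start (the participant's response latency), ms.
#' @param width_ms Window width, ms.
#' @return Non-negative scalar gain.
#' @export
feedback_gain <- function(mean_a, mean_b, start_ms, width_ms) {
  abs(trace_integral(mean_a, start_ms, width_ms) -
        trace_integral(mean_b, start_ms, width_ms))
}

#' Reward log-ratio of feedback gains
#'
#' `G = ln(gain_rewarded / gain_nonrewarded)`; 0 means no reward modulation.
#' The ratio normalizes gains within participants; the log linearizes it.
#' Undefined (NA) if either gain is non-positive; such pairs are excluded
#' from the paired statistics with a logged count.
#'
#' @param gain_rewarded,gain_nonrewarded Non-negative gains.
#' @return `G`, or `NA` if undefined.
#' @export
gain_log_ratio <- function(gain_rewarded, gain_nonrewarded) {
  ifelse(gain_rewarded > 0 & gain_nonrewarded > 0,
         log(gain_rewarded / gain_nonrewarded), NA_real_)
}

#' Reaction time from the processed triceps EMG
#'
#' The reaction time is the first time at or after the alignment event
#' (t = 0, the corrected perturbation onset) at which the processed EMG
#' stays strictly above `baseline mean + k_sd * baseline sd` for `run_ms`
#' consecutive milliseconds. Trials never meeting the criterion are flagged
#' discarded.
#'
#' @param trial A processed `trial_recording`, aligned to the perturbation.
#' @param baseline `baseline_stats` for the trial (see [trial_baseline()]).
#' @param muscle Muscle checked (triceps by convention).
#' @param k_sd Threshold in baseline standard deviations.
#' @param run_ms Required supra-threshold run, ms.
#' @return A `reaction_time_result`: `trial_id`, `rt_ms` (NA if discarded),
#'   `discarded`, `threshold`.
#' @export
detect_reaction_time <- function(trial, baseline, muscle = "triceps_lat",
                                 k_sd = 3, run_ms = 5) {
  thr <- baseline$stats["mean", muscle] + k_sd * baseline$stats["sd", muscle]
  sel <- trial$time_ms >= 0
  x <- trial$emg[sel, muscle]
  t <- trial$time_ms[sel]
  run_n <- round(run_ms * trial$fs / 1000)
  above <- x > thr
  # first index starting a run of run_n consecutive TRUE
  rt <- NA_real_
  if (length(above) >= run_n) {
    csum <- cumsum(as.integer(above))
    runsum <- csum[run_n:length(csum)] - c(0, csum)[1:(length(csum) - run_n + 1)]
    hit <- which(runsum == run_n)
    if (length(hit) > 0) rt <- t[hit[1]]
  }
  structure(list(trial_id = trial$trial_id, rt_ms = rt,
                 discarded = is.na(rt), threshold = thr,
                 criterion = list(k_sd = k_sd, run_ms = run_ms)),
            class = "reaction_time_result")
}

#' Anticipatory-EMG control check
#'
#' For tasks with a fixed target-to-perturbation interval (the In-Out task),
#' participants could in principle anticipate the perturbation. The check
#' compares mean triceps EMG in the 20 ms window immediately before the
#' perturbation onset between the contrasted conditions, per reward
#' condition, with a paired signed-rank test across participants.
#'
#' @param dataset A processed `emg_dataset`.
#' @param contrast Name of the contrast in the design.
#' @param muscle Muscle checked.
#' @param window_ms Width of the pre-perturbation window, ms.
#' @return A list of `signed_rank_result`, one per reward condition.
#' @export
anticipatory_check <- function(dataset, contrast = "slr",
                               muscle = "triceps_lat", window_ms = 20) {
  design <- dataset$design
  ct <- design$contrasts[[contrast]]
  if (is.null(ct)) stopf("design has no contrast '%s'", contrast)
  corr <- design$constants$onset_correction_ms
  pre_mean <- function(trials) {
    vals <- vapply(trials, function(tr) {
      tr <- align_trial(tr, "perturbation", corr)
      sel <- tr$time_ms >= -window_ms & tr$time_ms < 0
      mean(tr$emg[sel, muscle])
    }, numeric(1))
    mean(vals)
  }
  out <- list()
  for (rw in design$factors$reward) {
    a_means <- b_means <- numeric(0)
    for (p in dataset$participants) {
      sel_a <- c(ct$a, list(reward = rw))
      sel_b <- c(ct$b, list(reward = rw))
      a_means <- c(a_means, pre_mean(filter_trials(dataset$trials, sel_a, p)))
      b_means <- c(b_means, pre_mean(filter_trials(dataset$trials, sel_b, p)))
    }
    out[[rw]] <- signed_rank(a_means, b_means)
  }
  out
}
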