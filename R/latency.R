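# Response-latency estimation: per-sample ROC discrimination between two
# trial sets, sustained 25-75% AUC threshold crossing, and two-segment
# SSR-minimizing regression for the divergence onset.

#' Time-resolved ROC discrimination between two trial sets
#'
#' At every sample in the analysis window, computes the probability that a
#' randomly drawn trial from set A exceeds a randomly drawn trial from set B
#' (the Mann-Whitney construction; ties count 1/2). Uses all trials without
#' averaging. AUC = 0.5 means indiscriminable; the statistic is rank-based,
#' hence invariant to any common strictly monotone transform of the EMG.
#'
#' @param trials_a,trials_b Lists of processed, aligned `trial_recording`s
#'   (at least 2 per side), all covering `window_ms`.
#' @param muscle Muscle channel to discriminate.
#' @param window_ms Analysis window relative to the alignment event.
#' @return An `auc_trace`: list with `times`, `auc`, `n_a`, `n_b`.
#' @export
auc_trace <- function(trials_a, trials_b, muscle, window_ms = c(-100, 300)) {
  if (length(trials_a) < 2 || length(trials_b) < 2) {
    stopf("need at least 2 trials per side")
  }
  grab <- function(tr) {
    sel <- tr$time_ms >= window_ms[1] & tr$time_ms <= window_ms[2]
    if (sum(sel) != diff(window_ms) + 1) {
      stopf("trial does not cover the analysis window")
    }
    tr$emg[sel, muscle]
  }
  A <- vapply(trials_a, grab, numeric(diff(window_ms) + 1))
  B <- vapply(trials_b, grab, numeric(diff(window_ms) + 1))
  n_a <- ncol(A); n_b <- ncol(B)
  auc <- vapply(seq_len(nrow(A)), function(i) {
    r <- rank(c(A[i, ], B[i, ]))
    (sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2) / (n_a * n_b)
  }, numeric(1))
  structure(list(times = seq(window_ms[1], window_ms[2]), auc = auc,
                 n_a = n_a, n_b = n_b), class = "auc_trace")
}

#' First sustained crossing of the 25-75% AUC band
#'
#' Returns the first index at which two consecutive samples lie beyond the
#' symmetric discrimination band (both above `hi` or both below `lo`), or
#' `NA` if the band is never crossed for `run` consecutive samples.
#'
#' @param trace An `auc_trace`.
#' @param lo,hi Band edges.
#' @param run Required number of consecutive supra-threshold samples.
#' @return List with `index` (or `NA`) and `direction` (`"above"`,
#'   `"below"`, or `NA`).
#' @export
detect_crossing <- function(trace, lo = 0.25, hi = 0.75, run = 2) {
  auc <- trace$auc
  n <- length(auc)
  if (n < run) return(list(index = NA_integer_, direction = NA_character_))
  for (i in seq_len(n - run + 1)) {
    seg <- auc[i:(i + run - 1)]
    if (all(seg > hi)) return(list(index = i, direction = "above"))
    if (all(seg < lo)) return(list(index = i, direction = "below"))
  }
  list(index = NA_integer_, direction = NA_character_)
}

# SSE of a single least-squares line through (x, y).
line_sse <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  if (sxx == 0) return(syy)
  syy - sxy^2 / sxx
}

line_slope <- function(x, y) {
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(0)
  sum((x - mx) * (y - mean(y))) / sxx
}

#' Segmented-regression onset of an AUC trace
#'
#' Exhaustive search for the breakpoint that minimizes the summed squared
#' residuals of two independent least-squares lines fitted to the AUC before
#' its threshold crossing: one over `[fit_start, bp]` and one over
#' `[bp, crossing]` (the breakpoint sample belongs to both). The divergence
#' latency is the time of the minimizing breakpoint; SSE ties break toward
#' the earliest breakpoint.
#'
#' @param trace An `auc_trace`.
#' @param fit_start_index First sample of the pre-crossing fit window.
#' @param crossing_index Index returned by [detect_crossing()].
#' @param min_segment Minimum samples per segment.
#' @param direction Crossing direction (stored on the estimate).
#' @return A `latency_estimate`: `latency_ms`, `breakpoint_index`,
#'   `crossing_index`, `direction`, `sse`, `pre_slope`, `post_slope`,
#'   `valid`, `reason`.
#' @export
segmented_fit <- function(trace, fit_start_index, crossing_index,
                          min_segment = 3, direction = NA_character_) {
  invalid <- function(reason) {
    structure(list(latency_ms = NA_real_, breakpoint_index = NA_integer_,
                   crossing_index = crossing_index, direction = direction,
                   sse = NA_real_, pre_slope = NA_real_,
                   post_slope = NA_real_, valid = FALSE, reason = reason),
              class = "latency_estimate")
  }
  if (is.na(crossing_index)) return(invalid("no threshold crossing"))
  if (crossing_index - fit_start_index + 1 < 2 * min_segment - 1) {
    return(invalid("pre-crossing window too short for two segments"))
  }
  idx <- fit_start_index:crossing_index
  x <- trace$times[idx]
  y <- trace$auc[idx]
  candidates <- (fit_start_index + min_segment - 1):(crossing_index - min_segment + 1)
  best <- NULL
  for (bp in candidates) {
    i1 <- seq(fit_start_index, bp) - fit_start_index + 1
    i2 <- seq(bp, crossing_index) - fit_start_index + 1
    sse <- line_sse(x[i1], y[i1]) + line_sse(x[i2], y[i2])
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(bp = bp, sse = sse, i1 = i1, i2 = i2)
    }
  }
  structure(list(
    latency_ms = trace$times[best$bp],
    breakpoint_index = best$bp,
    crossing_index = crossing_index,
    direction = direction,
    sse = best$sse,
    pre_slope = line_slope(x[best$i1], y[best$i1]),
    post_slope = line_slope(x[best$i2], y[best$i2]),
    valid = TRUE, reason = NA_character_
  ), class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("latency_estimate: %g ms (crossing %s at index %d, SSE %.4g)\n",
                x$latency_ms, x$direction, x$crossing_index, x$sse))
  } else {
    cat(sprintf("latency_estimate: invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' Divergence latency between two contrasted trial sets
#'
#' Composes [auc_trace()], [detect_crossing()] and [segmented_fit()] over
#' the analysis window. Trials should already be filtered to one participant
#' and one reward condition, processed, and aligned to the contrast event.
#'
#' @param trials_a,trials_b Lists of processed, aligned trials.
#' @param muscle Muscle channel used for discrimination.
#' @param window_ms Analysis window, ms, relative to the alignment event.
#' @param fit_start `"event"` anchors the pre-crossing fit at t = 0 (use for
#'   mechanical contrasts); `"window"` anchors it at the window start (use
#'   for visual contrasts, where pre-event activity is movement-related).
#' @param lo,hi,run Crossing-band parameters; see [detect_crossing()].
#' @param min_segment Minimum samples per regression segment.
#' @return A `latency_estimate`; invalid (with a reason) if the band is
#'   never crossed.
#' @export
estimate_latency <- function(trials_a, trials_b, muscle,
                             window_ms = c(-100, 300),
                             fit_start = c("event", "window"),
                             lo = 0.25, hi = 0.75, run = 2, min_segment = 3) {
  fit_start <- match.arg(fit_start)
  trace <- auc_trace(trials_a, trials_b, muscle, window_ms)
  cross <- detect_crossing(trace, lo, hi, run)
  start_idx <- if (fit_start == "event") which(trace$times == 0) else 1L
  if (length(start_idx) == 0) start_idx <- 1L
  est <- segmented_fit(trace, start_idx, cross$index,
                       min_segment = min_segment,
                       direction = cross$direction)
  est$trace <- trace
  est
}
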