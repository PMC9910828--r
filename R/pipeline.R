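# End-to-end analysis pipeline: preprocessing, behavior (movement times),
# response latencies, feedback gains and reward log-ratios, reaction times
# (RT task), anticipatory control check, and paired statistics.

#' Run the full reward-feedback analysis on a dataset
#'
#' Reproduces the per-experiment analysis sequence on a synthetic or
#' user-supplied dataset: preprocess the EMG, compare per-participant median
#' movement times between reward conditions, estimate the contrast's
#' divergence latency per participant and reward condition (ROC + segmented
#' regression), integrate feedback gains in a window anchored at each
#' participant's own latency (or per-trial reaction time in the RT task),
#' test the reward log-ratio of gains per muscle, and - for the In-Out
#' task - run the anticipatory-EMG control check. Anchoring the gain window
#' at the measured latency (never a fixed window) avoids mistaking a latency
#' shift for a gain change.
#'
#' @param dataset An `emg_dataset`.
#' @param contrast Contrast name; defaults to the design's first contrast.
#' @param window_ms ROC analysis window, ms, around the alignment event.
#' @param gain_muscles Muscles to quantify gains for; defaults to all
#'   recorded muscles.
#' @return A `reward_report`.
#' @export
run_pipeline <- function(dataset, contrast = NULL,
                         window_ms = c(-100, 300), gain_muscles = NULL) {
  design <- dataset$design
  contrast <- contrast %||% names(design$contrasts)[1]
  ct <- design$contrasts[[contrast]]
  if (is.null(ct)) stopf("design has no contrast '%s'", contrast)
  gain_muscles <- gain_muscles %||% dataset$config$muscles %||%
    colnames(dataset$trials[[1]]$emg)
  if (!identical(dataset$trials[[1]]$emg_state, "processed")) {
    dataset <- preprocess_dataset(dataset)
  }

  report <- list(task = design$task_id, contrast = contrast,
                 n_participants = length(dataset$participants))
  report$mt <- median_mt_contrast(dataset)

  if (design$task_id == "proprio_rt") {
    report <- c(report, rt_pipeline(dataset, ct, gain_muscles))
  } else {
    report <- c(report, latency_gain_pipeline(dataset, ct, window_ms,
                                              gain_muscles))
    if (design$task_id == "in_out") {
      report$anticipatory <- anticipatory_check(dataset, contrast = "slr")
    }
  }
  structure(report, class = "reward_report")
}

# Latency + gain arm shared by the four perturbation/jump tasks.
latency_gain_pipeline <- function(dataset, ct, window_ms, gain_muscles) {
  design <- dataset$design
  corr <- design$constants$onset_correction_ms
  rewards <- design$factors$reward
  fit_start <- ct$fit_start %||% "event"

  lat_rows <- list()
  gain_rows <- list()
  for (p in dataset$participants) {
    aligned <- list()
    for (rw in rewards) {
      trials_a <- lapply(filter_trials(dataset$trials,
                                       c(ct$a, list(reward = rw)), p),
                         align_trial, event = ct$align_event,
                         onset_correction_ms = corr)
      trials_b <- lapply(filter_trials(dataset$trials,
                                       c(ct$b, list(reward = rw)), p),
                         align_trial, event = ct$align_event,
                         onset_correction_ms = corr)
      est <- estimate_latency(trials_a, trials_b, ct$muscle,
                              window_ms = window_ms, fit_start = fit_start)
      lat_rows[[paste(p, rw)]] <- data.frame(
        participant = p, reward = rw, latency_ms = est$latency_ms,
        valid = est$valid, sse = est$sse)
      aligned[[rw]] <- list(a = trials_a, b = trials_b, latency = est)
    }
    for (m in gain_muscles) {
      for (rw in rewards) {
        est <- aligned[[rw]]$latency
        gain <- NA_real_
        if (est$valid &&
            est$latency_ms + ct$width_ms <= window_ms[2]) {
          gain <- feedback_gain(mean_trace(aligned[[rw]]$a, m, window_ms),
                                mean_trace(aligned[[rw]]$b, m, window_ms),
                                est$latency_ms, ct$width_ms)
        }
        gain_rows[[paste(p, m, rw)]] <- data.frame(
          participant = p, muscle = m, reward = rw, gain = gain)
      }
    }
  }
  lat_tab <- do.call(rbind, lat_rows); rownames(lat_tab) <- NULL
  gain_tab <- do.call(rbind, gain_rows); rownames(gain_tab) <- NULL
  list(latency = finish_latency(lat_tab),
       gains = finish_gains(gain_tab, gain_muscles))
}

# RT-task arm: per-trial reaction times anchor per-trial gain windows.
rt_pipeline <- function(dataset, ct, gain_muscles) {
  design <- dataset$design
  corr <- design$constants$onset_correction_ms
  rewards <- design$factors$reward
  width <- ct$width_ms

  rt_rows <- list()
  gain_rows <- list()
  for (p in dataset$participants) {
    for (rw in rewards) {
      trs <- filter_trials(dataset$trials, list(reward = rw), p)
      integrals <- stats::setNames(
        rep(list(numeric(0)), length(gain_muscles)), gain_muscles)
      for (tr in trs) {
        bl <- trial_baseline(tr, design)
        tr <- align_trial(tr, "perturbation", corr)
        res <- detect_reaction_time(tr, bl, muscle = ct$muscle)
        rt_rows[[length(rt_rows) + 1L]] <- data.frame(
          participant = p, trial_id = tr$trial_id, reward = rw,
          rt_ms = res$rt_ms %||% NA_real_, discarded = res$discarded)
        if (res$discarded) next
        for (m in gain_muscles) {
          trace <- list(times = tr$time_ms, mean = tr$emg[, m])
          integrals[[m]] <- c(integrals[[m]],
                              trace_integral(trace, res$rt_ms, width))
        }
      }
      for (m in gain_muscles) {
        gain_rows[[paste(p, m, rw)]] <- data.frame(
          participant = p, muscle = m, reward = rw,
          gain = if (length(integrals[[m]])) mean(integrals[[m]]) else NA_real_)
      }
    }
  }
  rt_tab <- do.call(rbind, rt_rows); rownames(rt_tab) <- NULL
  gain_tab <- do.call(rbind, gain_rows); rownames(gain_tab) <- NULL

  med <- stats::aggregate(rt_ms ~ participant + reward,
                          data = rt_tab[!rt_tab$discarded, ], FUN = stats::median)
  wide <- stats::reshape(med, idvar = "participant", timevar = "reward",
                         direction = "wide")
  rt_test <- tryCatch(
    signed_rank(wide$rt_ms.rewarded, wide$rt_ms.non_rewarded),
    error = function(e) NULL)

  list(rt = list(table = rt_tab,
                 n_discarded = sum(rt_tab$discarded),
                 medians = wide, test = rt_test),
       gains = finish_gains(gain_tab, gain_muscles))
}

finish_latency <- function(lat_tab) {
  wide <- merge(lat_tab[lat_tab$reward == "rewarded",
                        c("participant", "latency_ms", "valid")],
                lat_tab[lat_tab$reward == "non_rewarded",
                        c("participant", "latency_ms", "valid")],
                by = "participant", suffixes = c("_rewarded", "_nonrewarded"))
  ok <- wide$valid_rewarded & wide$valid_nonrewarded
  test <- if (sum(ok) >= 5) {
    tryCatch(signed_rank(wide$latency_ms_rewarded[ok],
                         wide$latency_ms_nonrewarded[ok]),
             error = function(e) NULL)
  }
  list(table = lat_tab, n_valid_pairs = sum(ok), test = test)
}

finish_gains <- function(gain_tab, gain_muscles) {
  tests <- list()
  n_excluded <- 0L
  rows <- list()
  for (m in gain_muscles) {
    gm <- gain_tab[gain_tab$muscle == m, ]
    wide <- merge(gm[gm$reward == "rewarded", c("participant", "gain")],
                  gm[gm$reward == "non_rewarded", c("participant", "gain")],
                  by = "participant",
                  suffixes = c("_rewarded", "_nonrewarded"))
    wide$G <- gain_log_ratio(wide$gain_rewarded, wide$gain_nonrewarded)
    ok <- !is.na(wide$G)
    n_excluded <- n_excluded + sum(!ok)
    tests[[m]] <- if (sum(ok) >= 5) {
      tryCatch(signed_rank(wide$gain_rewarded[ok], wide$gain_nonrewarded[ok]),
               error = function(e) NULL)
    }
    wide$muscle <- m
    rows[[m]] <- wide
  }
  list(table = gain_tab, log_ratios = do.call(rbind, rows),
       tests = tests, n_excluded = n_excluded)
}

#' @export
print.reward_report <- function(x, ...) {
  fmt_test <- function(t) {
    if (is.null(t)) return("n/a")
    pfmt <- if (t$p < 1e-3) sprintf("%.2e", t$p) else sprintf("%.3g", t$p)
    sprintf("W = %g, r = %.2f, p = %s (n = %d)", t$W, t$r, pfmt, t$n)
  }
  cat(sprintf("Reward-feedback report: task '%s', contrast '%s', %d participants\n",
              x$task, x$contrast, x$n_participants))
  cat("  Movement time (rewarded - non-rewarded): median diff",
      sprintf("%.1f ms;", stats::median(x$mt$per_participant$diff)),
      fmt_test(x$mt$test), "\n")
  if (!is.null(x$latency)) {
    cat("  Latency (paired across reward):", fmt_test(x$latency$test),
        sprintf("[%d valid pairs]\n", x$latency$n_valid_pairs))
  }
  if (!is.null(x$rt)) {
    cat(sprintf("  Reaction time: %d trials discarded;", x$rt$n_discarded),
        fmt_test(x$rt$test), "\n")
  }
  if (!is.null(x$gains)) {
    for (m in names(x$gains$tests)) {
      G <- x$gains$log_ratios$G[x$gains$log_ratios$muscle == m]
      cat(sprintf("  Gain %-16s median G = %+.3f; %s\n", paste0(m, ":"),
                  stats::median(G, na.rm = TRUE), fmt_test(x$gains$tests[[m]])))
    }
  }
  if (!is.null(x$anticipatory)) {
    for (rw in names(x$anticipatory)) {
      cat(sprintf("  Anticipatory EMG (%s): %s\n", rw,
                  fmt_test(x$anticipatory[[rw]])))
    }
  }
  invisible(x)
}

#' Persist a report's tables
#'
#' Writes the per-participant tables as CSV and a summary of the test
#' statistics as JSON.
#'
#' @param report A `reward_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$mt$per_participant,
                   file.path(dir, "movement_times.csv"), row.names = FALSE)
  if (!is.null(report$latency)) {
    utils::write.csv(report$latency$table,
                     file.path(dir, "latencies.csv"), row.names = FALSE)
  }
  if (!is.null(report$rt)) {
    utils::write.csv(report$rt$table,
                     file.path(dir, "reaction_times.csv"), row.names = FALSE)
  }
  if (!is.null(report$gains)) {
    utils::write.csv(report$gains$log_ratios,
                     file.path(dir, "gains.csv"), row.names = FALSE)
  }
  tidy_test <- function(t) {
    if (is.null(t)) NULL else t[c("n", "W", "r", "p", "method")]
  }
  summary <- list(
    task = report$task, contrast = report$contrast,
    mt_test = tidy_test(report$mt$test),
    latency_test = tidy_test(report$latency$test),
    rt_test = tidy_test(report$rt$test),
    gain_tests = if (!is.null(report$gains))
      lapply(report$gains$tests, tidy_test)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
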