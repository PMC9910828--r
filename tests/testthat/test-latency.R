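# Construct an auc_trace directly from a numeric vector.
as_trace <- function(auc, times = seq_along(auc) - 1) {
  structure(list(times = times, auc = auc, n_a = 10, n_b = 10),
            class = "auc_trace")
}

# Trials with prescribed EMG values at each time sample, for oracle checks.
value_trials <- function(mat, times = seq_len(nrow(mat)) - 1 - 100) {
  lapply(seq_len(ncol(mat)), function(j) {
    tr <- toy_trial(n = nrow(mat))
    tr$time_ms <- times
    tr$emg[, "triceps_lat"] <- mat[, j]
    tr
  })
}

test_that("per-sample AUC equals the exhaustive pairwise count", {
  set.seed(42)
  nt <- 14
  A <- matrix(rnorm(401 * 6, mean = 1), 401, 6)
  B <- matrix(rnorm(401 * 8), 401, 8)
  # ties at a few samples
  A[5, ] <- 1; B[5, ] <- 1
  A[9, 1:3] <- B[9, 1:3] <- 0.5
  trace <- auc_trace(value_trials(abs(A)), value_trials(abs(B)), "triceps_lat")
  # brute-force oracle over all (a, b) pairs with ties counted 1/2
  oracle <- vapply(seq_len(401), function(i) {
    a <- abs(A)[i, ]; b <- abs(B)[i, ]
    s <- 0
    for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s / (length(a) * length(b))
  }, numeric(1))
  expect_equal(trace$auc, oracle, tolerance = 1e-12)
  expect_true(all(trace$auc >= 0 & trace$auc <= 1))
  expect_identical(c(trace$n_a, trace$n_b), c(6L, 8L))
  expect_error(auc_trace(value_trials(abs(A)), list(), "triceps_lat"),
               "2 trials")
})

test_that("AUC is rank-based: monotone transforms and swaps behave", {
  set.seed(7)
  A <- matrix(abs(rnorm(401 * 5, 2)), 401, 5)
  B <- matrix(abs(rnorm(401 * 5, 1)), 401, 5)
  t1 <- auc_trace(value_trials(A), value_trials(B), "triceps_lat")
  # strictly monotone transform of all amplitudes leaves the AUC unchanged
  t2 <- auc_trace(value_trials(log1p(3 * A)), value_trials(log1p(3 * B)),
                  "triceps_lat")
  expect_equal(t1$auc, t2$auc)
  # swapping the sides maps auc -> 1 - auc
  t3 <- auc_trace(value_trials(B), value_trials(A), "triceps_lat")
  expect_equal(t3$auc, 1 - t1$auc)
})

test_that("crossing detection requires two consecutive samples beyond the band", {
  base <- rep(0.5, 60)
  # one isolated extreme sample is not a crossing
  x <- base; x[30] <- 0.9
  expect_true(is.na(detect_crossing(as_trace(x))$index))
  # a sustained step above is found at its first sample
  x <- base; x[25:60] <- 0.8
  expect_identical(detect_crossing(as_trace(x))$index, 25L)
  # the band is symmetric: sustained drop below 0.25 counts too
  x <- base; x[40:60] <- 0.1
  cr <- detect_crossing(as_trace(x))
  expect_identical(cr$index, 40L)
  expect_identical(cr$direction, "below")
  # exactly at the threshold does not count (strictly beyond)
  x <- base; x[10:60] <- 0.75
  expect_true(is.na(detect_crossing(as_trace(x))$index))
})

test_that("segmented fit finds a noiseless elbow exactly", {
  times <- 0:60
  elbow <- 35
  auc <- ifelse(times <= elbow, 0.5, 0.5 + 0.02 * (times - elbow))
  trace <- as_trace(auc, times)
  cross <- detect_crossing(trace)
  est <- segmented_fit(trace, 1L, cross$index, direction = cross$direction)
  expect_true(est$valid)
  expect_identical(est$breakpoint_index, which(times == elbow))
  expect_equal(est$latency_ms, elbow)
  expect_lt(est$sse, 1e-12)
  expect_equal(est$pre_slope, 0, tolerance = 1e-12)
  expect_equal(est$post_slope, 0.02, tolerance = 1e-12)
})

test_that("segmented fit equals an exhaustive lm-based breakpoint search", {
  set.seed(11)
  for (case in 1:5) {
    times <- 0:80
    auc <- pmin(pmax(0.5 + cumsum(rnorm(81, 0.002, 0.02)), 0), 1)
    trace <- as_trace(auc, times)
    crossing <- 70L
    est <- segmented_fit(trace, 5L, crossing)
    # independent oracle: lm() per candidate breakpoint
    sses <- vapply(7:(crossing - 2), function(bp) {
      i1 <- 5:bp; i2 <- bp:crossing
      sum(stats::resid(stats::lm(auc[i1] ~ times[i1]))^2) +
        sum(stats::resid(stats::lm(auc[i2] ~ times[i2]))^2)
    }, numeric(1))
    expect_equal(est$sse, min(sses), tolerance = 1e-10)
    expect_identical(est$breakpoint_index,
                     as.integer((7:(crossing - 2))[which.min(sses)]))
  }
  # too-short windows are flagged, not fitted
  short <- segmented_fit(as_trace(rep(0.5, 10)), 1L, 4L)
  expect_false(short$valid)
  expect_match(short$reason, "short")
})

test_that("latency recovery error shrinks with the trial count", {
  d <- task_design("in_out")
  cfg <- recovery_config(d, latency_ms = 50)
  sc <- make_scalars(cfg, 3001)
  err_at_n <- function(n_side, seeds) {
    vapply(seeds, function(s) {
      a <- sim_trials(d, cond_a(), cfg, sc, n_side, seed_mix(3000, s), 1L)
      b <- sim_trials(d, cond_b(), cfg, sc, n_side, seed_mix(3000, s), 2L)
      est <- estimate_latency(a, b, "triceps_lat")
      if (est$valid) abs(est$latency_ms - 50) else NA_real_
    }, numeric(1))
  }
  e10 <- err_at_n(10, 1:12)
  e30 <- err_at_n(30, 13:24)
  e100 <- err_at_n(100, 25:32)
  expect_gte(median(e10, na.rm = TRUE), median(e100, na.rm = TRUE))
  expect_lte(median(e100, na.rm = TRUE), 6)
})

test_that("latency estimation is invariant to common positive scaling", {
  d <- task_design("in_out")
  cfg <- recovery_config(d, latency_ms = 50)
  sc <- make_scalars(cfg, 3101)
  a <- sim_trials(d, cond_a(), cfg, sc, 30, 3102, 1L)
  b <- sim_trials(d, cond_b(), cfg, sc, 30, 3102, 2L)
  scale_trial <- function(tr) { tr$emg <- tr$emg * 7.3; tr }
  e1 <- estimate_latency(a, b, "triceps_lat")
  e2 <- estimate_latency(lapply(a, scale_trial), lapply(b, scale_trial),
                         "triceps_lat")
  expect_equal(e1$latency_ms, e2$latency_ms)
  expect_equal(e1$trace$auc, e2$trace$auc)
})

test_that("swapping contrast sides leaves the detected latency unchanged", {
  d <- task_design("in_out")
  cfg <- recovery_config(d, latency_ms = 50)
  sc <- make_scalars(cfg, 3201)
  a <- sim_trials(d, cond_a(), cfg, sc, 40, 3202, 1L)
  b <- sim_trials(d, cond_b(), cfg, sc, 40, 3202, 2L)
  e_ab <- estimate_latency(a, b, "triceps_lat")
  e_ba <- estimate_latency(b, a, "triceps_lat")
  expect_equal(e_ba$trace$auc, 1 - e_ab$trace$auc)
  expect_equal(e_ba$latency_ms, e_ab$latency_ms)
  expect_false(identical(e_ab$direction, e_ba$direction))
})
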