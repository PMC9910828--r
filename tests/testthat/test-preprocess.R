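test_that("band-pass removes DC and passes mid-band content", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  # DC input -> essentially zero everywhere
  out_dc <- bandpass(rep(2.5, length(t)), fs = fs)
  expect_lt(max(abs(out_dc)), 1e-6 * 2.5)
  # 100 Hz unit sinusoid: steady-state amplitude in [0.9, 1]
  x100 <- sin(2 * pi * 100 * t)
  out <- bandpass(x100, fs = fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  amp <- sqrt(2 * mean(out[mid]^2)) # RMS-based amplitude of the sinusoid
  expect_gte(amp, 0.9)
  expect_lte(amp, 1.0)
  # independent oracle: |H|^2 from the filter's own frequency response
  bf <- signal::butter(2, c(20, 250) / (fs / 2), type = "pass")
  H <- signal::freqz(bf$b, bf$a, Fs = fs, n = 2048)
  h100 <- abs(H$h[which.min(abs(H$f - 100))])^2
  expect_equal(amp, h100, tolerance = 0.02)
  # 1 Hz: strongly attenuated
  out1 <- bandpass(sin(2 * pi * 1 * t), fs = fs)
  expect_lt(sqrt(2 * mean(out1[mid]^2)), 0.05)
})

test_that("band-pass has zero phase: a symmetric pulse keeps its peak time", {
  fs <- 1000
  n <- 1500
  x <- exp(-((seq_len(n) - 700)^2) / (2 * 15^2))
  out <- bandpass(x, fs = fs)
  expect_lte(abs(which.max(out) - 700), 1)
  expect_error(bandpass(x[1:4], fs = fs), "short")
})

test_that("rectification is the absolute value and idempotent", {
  expect_identical(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_identical(rectify(numeric(5)), numeric(5))
  x <- rnorm(100)
  expect_identical(rectify(rectify(x)), rectify(x))
})

test_that("normalization scalar pools exactly 6000 samples from four holds", {
  fs <- 1000
  mk_cal <- function(levels) {
    holds <- lapply(levels, function(l) {
      matrix(l, 2000, 1, dimnames = list(NULL, "triceps_lat"))
    })
    structure(list(holds = holds, entry_ms = rep(0, 4), fs = fs,
                   state = "processed"), class = "calibration_set")
  }
  # constant level c -> scalar c; mixed levels -> mean of concatenation
  expect_equal(unclass(normalization_scalar(mk_cal(rep(2, 4)))),
               c(triceps_lat = 2))
  expect_equal(unclass(normalization_scalar(mk_cal(c(1, 1, 3, 3)))),
               c(triceps_lat = 2))
  # window arithmetic: marking samples outside [250, 1750) must not matter
  holds <- lapply(1:4, function(i) {
    h <- matrix(5, 2000, 1, dimnames = list(NULL, "triceps_lat"))
    h[c(1:250, 1751:2000), 1] <- 1e6
    h
  })
  cal <- structure(list(holds = holds, entry_ms = rep(0, 4), fs = fs,
                        state = "processed"), class = "calibration_set")
  expect_equal(unclass(normalization_scalar(cal)), c(triceps_lat = 5))
  expect_error(normalization_scalar(mk_cal(rep(0, 4))), "degenerate")
  expect_error(normalization_scalar(mk_cal(rep(1, 3))[
    c("holds", "entry_ms", "fs", "state")]), "calibration_set")
})

test_that("with noise the scalar tracks the mean rectified level across seeds", {
  d <- task_design("in_out")
  cfg <- synth_config(d, muscles = "triceps_lat",
                      baseline_level = c(triceps_lat = 1))
  scalars <- vapply(1:40, function(s)
    make_scalars(cfg, 10000 + s)[["triceps_lat"]], numeric(1))
  # Monte-Carlo oracle: pooled mean rectified level of fresh holds
  ref <- mean(vapply(41:60, function(s) {
    cal <- process_calibration(simulate_calibration(cfg, 10000 + s))
    mean(vapply(cal$holds, function(h) mean(h[, 1]), numeric(1)))
  }, numeric(1)))
  expect_lt(abs(mean(scalars) / ref - 1), 0.02)
})

test_that("normalization is linear and invertible", {
  sc <- structure(c(triceps_lat = 2.5), class = "normalization_scalars")
  x <- abs(rnorm(50))
  expect_equal(normalize_emg(rep(2.5, 10), sc, "triceps_lat"), rep(1, 10))
  expect_equal(normalize_emg(3 * x, sc, "triceps_lat"),
               3 * normalize_emg(x, sc, "triceps_lat"))
  expect_equal(normalize_emg(x, sc, "triceps_lat") * 2.5, x)
  expect_error(normalize_emg(x, sc, "biceps"), "biceps")
})

test_that("alignment shifts the time base by the corrected event time", {
  tr <- toy_trial()
  al <- align_trial(tr, "perturbation", onset_correction_ms = 4)
  # perturbation logged at 800 -> sample formerly at 804 ms becomes t = 0
  expect_equal(al$time_ms[tr$time_ms == 804], 0)
  expect_equal(al$events[["perturbation"]], -4)
  # zero correction is a pure re-indexing; realigning is idempotent
  al0 <- align_trial(tr, "perturbation")
  expect_equal(al0$time_ms[tr$time_ms == 800], 0)
  expect_equal(align_trial(al, "perturbation", 4)$time_ms, al$time_ms)
  expect_error(align_trial(tr, "jump"), "jump")
})

test_that("trial baseline covers exactly the 50 ms window before its event", {
  d <- task_design("in_out")
  tr <- toy_trial()
  # constant 1.0 -> mean 1, sd 0
  bl <- trial_baseline(tr, d)
  expect_equal(unname(bl$stats["mean", "triceps_lat"]), 1)
  expect_equal(unname(bl$stats["sd", "triceps_lat"]), 0)
  # mark everything outside [-350, -300) before the perturbation (at 800)
  tr2 <- toy_trial()
  tr2$emg[, 1] <- 100
  tr2$emg[tr2$time_ms >= 450 & tr2$time_ms < 500, 1] <- 7
  bl2 <- trial_baseline(tr2, d)
  expect_equal(unname(bl2$stats["mean", "triceps_lat"]), 7)
  expect_equal(unname(bl2$stats["sd", "triceps_lat"]), 0)
  # the jump designs anchor to target appearance instead
  dj <- task_design("cursor_jump")
  tr3 <- toy_trial(events = c(target_onset = 600, perturbation = NA,
                              jump = 900, start_exit = NA,
                              target_entry = NA))
  tr3$emg[, 1] <- 100
  tr3$emg[tr3$time_ms >= 250 & tr3$time_ms < 300, 1] <- 3
  expect_equal(unname(trial_baseline(tr3, dj)$stats["mean", "triceps_lat"]), 3)
  # insufficient pre-event data
  tr4 <- toy_trial(n = 400)
  tr4$events[["perturbation"]] <- 100
  expect_error(trial_baseline(tr4, d), "insufficient")
})

test_that("the full chain calibrates processed EMG to the tonic level", {
  d <- task_design("in_out")
  cfg <- synth_config(d, muscles = c("triceps_lat", "biceps"),
                      baseline_level = c(triceps_lat = 1, biceps = 0.3))
  sc <- make_scalars(cfg, 77)
  # across many trials the pre-event processed mean converges to 1 in
  # normalization units for every muscle, whatever its raw tonic level
  trs <- lapply(1:80, function(i) {
    preprocess_trial(simulate_trial(d, cond_b(), cfg, seed = 400 + i), sc)
  })
  for (m in c("triceps_lat", "biceps")) {
    pre <- vapply(trs, function(tr) {
      mean(tr$emg[tr$time_ms >= 300 & tr$time_ms < 900, m])
    }, numeric(1))
    expect_lt(abs(mean(pre) - 1), 0.05)
  }
  expect_identical(trs[[1]]$emg_state, "processed")
  expect_true(all(trs[[1]]$emg >= 0))
})
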