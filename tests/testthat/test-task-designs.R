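test_that("all five designs load and satisfy their epoch arithmetic", {
  for (task in c("in_out", "target_selection", "cursor_jump", "target_jump",
                 "proprio_rt")) {
    d <- task_design(task)
    expect_s3_class(d, "task_design")
    n_combo <- prod(lengths(d$factors))
    expect_equal(d$epoch_size, d$copies_per_combo * n_combo)
  }
})

test_that("schedules have exact per-epoch combination counts and totals", {
  totals <- c(in_out = 336, target_selection = 224, cursor_jump = 312,
              target_jump = 312, proprio_rt = 108)
  for (task in names(totals)) {
    d <- task_design(task)
    sched <- make_schedule(d, seed = 7)
    expect_identical(nrow(sched), as.integer(totals[[task]]))
    combo_cols <- names(d$factors)
    for (e in unique(sched$epoch)) {
      counts <- table(do.call(paste, sched[sched$epoch == e, combo_cols,
                                           drop = FALSE]))
      expect_true(all(counts == d$copies_per_combo))
    }
  }
})

test_that("schedule blocks split epochs evenly", {
  sched <- make_schedule(task_design("in_out"), seed = 1)
  expect_identical(as.integer(table(sched$block)), rep(112L, 3))
  sched2 <- make_schedule(task_design("target_selection"), seed = 1)
  expect_identical(as.integer(table(sched2$block)), rep(112L, 2))
  # half of Target Selection trials carry two targets
  expect_identical(sum(sched2$n_targets == "two"), 112L)
})

test_that("schedules are a pure function of design and seed", {
  d <- task_design("cursor_jump")
  expect_identical(make_schedule(d, 123), make_schedule(d, 123))
  s1 <- make_schedule(d, 1)
  s2 <- make_schedule(d, 2)
  expect_false(identical(s1, s2))
  # each of the 6 condition combinations appears 312 / 6 = 52 times
  counts <- table(paste(s1$jump, s1$reward))
  expect_true(all(counts == 52))
})

test_that("malformed designs are rejected", {
  d <- task_design("in_out")
  d$epoch_size <- 15
  expect_error(make_schedule(d, 1), "epoch_size")
  d2 <- task_design("in_out")
  d2$contrasts$bad <- list(a = list(perturbation = "inward"),
                           b = list(target = "outward"), width_ms = 50)
  expect_error(validate_design <- emgreward:::validate_design(d2), "disjoint")
})

test_that("In-Out return follows the printed exponential in time-in-target", {
  p <- return_params("time_in_target", g_max = 15, tau = 1.428,
                     x0 = 500, xf = 800)
  expect_equal(in_out_return(800, p), 15)
  expect_equal(in_out_return(500, p), 15 * exp(-1.428), tolerance = 1e-12)
  expect_equal(in_out_return(650, p), 15 * exp(-0.714), tolerance = 1e-12)
  # monotone non-decreasing and bounded by (0, g_max] on a dense grid
  x <- seq(0, 800, by = 1)
  r <- in_out_return(x, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r > 0 & r <= 15 + 1e-12))
  expect_error(mt_return(100, p), "movement_time")
})

test_that("movement-time return is clipped, bounded and non-increasing", {
  p <- return_params("movement_time", g_max = 10, tau = 2.447,
                     scaler = 1, shifter = 0, mt_max = 728)
  expect_equal(mt_return(0, p), 10)
  expect_equal(mt_return(728, p), 10 * exp(-2.447), tolerance = 1e-12)
  mt <- seq(0, 5000, by = 5)
  r <- mt_return(mt, p)
  expect_true(all(diff(r) <= 1e-12))
  expect_true(all(r >= 0 & r <= 10 * (1 + 0)))
  # negative shifter: large MT clips to exactly zero
  p2 <- return_params("movement_time", g_max = 10, tau = 3.958,
                      scaler = 0.996, shifter = -0.041, mt_max = 2864)
  expect_equal(mt_return(1e6, p2), 0)
  expect_true(all(mt_return(mt, p2) <= 10 * (0.996 + -0.041) + 1e-12))
  expect_error(in_out_return(100, p), "time_in_target")
})

test_that("per-condition return parameters resolve from the design tables", {
  d <- task_design("in_out")
  p <- emgreward:::lookup_return_params(
    d, list(perturbation = "outward", target = "inward"))
  expect_equal(p$tau, 1.351)
  d2 <- task_design("target_jump")
  p2 <- emgreward:::lookup_return_params(d2, list(jump = "none"))
  expect_equal(p2$scaler, 0.683)
  expect_equal(p2$mt_max, 2882)
})

test_that("movement time follows the proprioceptive and visual definitions", {
  d <- task_design("in_out")
  # proprioceptive: event subtraction via first target entry
  tr <- toy_trial(n = 2000)
  tr$events[["perturbation"]] <- 0
  tr$kin[, "radial_pos"] <- c(rep(0, 612), rep(10, 1388)) # enters at 612 ms
  expect_equal(movement_time(tr, d), 612)
  # never entering the target flags the trial invalid
  tr$kin[, "radial_pos"] <- 0
  expect_true(is.na(movement_time(tr, d)))
})

test_that("simulated visual trials return their bookkept movement time", {
  d <- task_design("target_jump")
  cfg <- synth_config(d, muscles = "triceps_lat",
                      baseline_level = c(triceps_lat = 1))
  for (s in 1:5) {
    tr <- simulate_trial(d, list(jump = "inward", reward = "rewarded"),
                         cfg, seed = s)
    expect_equal(movement_time(tr, d), tr$ground_truth$mt_ms)
    # velocity criterion holds at the returned time
    t_mt <- tr$events[["start_exit"]] + tr$mt
    i <- which(tr$time_ms >= t_mt)[1]
    pos <- tr$kin[, "radial_pos"]
    vel <- (pos[i + 1] - pos[i - 1]) / 2 * 1000
    expect_lt(abs(vel), 10)
    expect_gte(pos[i], tr$geometry$target_distance_cm -
                 tr$geometry$target_radius_cm)
  }
})

test_that("trial returns dispatch on the design return form", {
  d <- task_design("in_out")
  cfg <- synth_config(d, muscles = "triceps_lat",
                      baseline_level = c(triceps_lat = 1))
  tr <- simulate_trial(d, cond_a("rewarded"), cfg, seed = 3)
  ret <- trial_return(tr, d)
  expect_true(ret > 0 && ret <= 15)
  tr_n <- simulate_trial(d, cond_a("non_rewarded"), cfg, seed = 3)
  expect_identical(trial_return(tr_n, d), 0)
})
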