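test_that("frame_counts reproduces the hand-enumerated conservation example", {
  counts <- frame_counts(two_frame_table(), tracking_window())
  expect_equal(counts$n_start, 2)  # A, B (D at x=40 is outside)
  expect_equal(counts$n_end, 3)    # A, C, D
  expect_equal(counts$n_new, 1)    # C: first seen, parent A in window
  expect_equal(counts$n_in, 1)     # D crosses in
  expect_equal(counts$n_out, 1)    # B crosses out
  expect_equal(counts$n_death, 0)
  expect_equal(counts$n_anomaly, 0)
  expect_equal(check_conservation(counts), 0)
})

test_that("a first-seen object without a window-resident parent counts as inflow", {
  # C's parent is D, which sat outside the window at the earlier frame
  counts <- frame_counts(two_frame_table(parent_of_c = "D"),
                         tracking_window())
  expect_equal(counts$n_new, 0)
  expect_equal(counts$n_in, 2)
  expect_equal(check_conservation(counts), 0)
})

test_that("death flags remove objects from the living count and feed n_death", {
  tab <- stationary_table(n = 5, n_frames = 6)
  tab <- annotate_deaths(tab, data.frame(fov = "f1", object_id = "c3",
                                         frame = 2))
  counts <- frame_counts(tab, tracking_window())
  expect_equal(counts$n_death, c(0, 1, 0, 0, 0))
  expect_equal(counts$n_start, c(5, 5, 4, 4, 4))
  expect_equal(check_conservation(counts), rep(0, 5))
})

test_that("frame_counts rejects degenerate input", {
  tab <- stationary_table(n = 3, n_frames = 1)
  expect_error(frame_counts(tab), "single-frame")
  multi <- stationary_table(n = 2, n_frames = 3)
  multi2 <- multi
  multi2$fov <- "f2"
  both <- tracked_table(rbind(as.data.frame(multi), as.data.frame(multi2)))
  expect_error(frame_counts(both), "single field of view")
})

test_that("mean_rate recovers an exact slope on a perfect line", {
  # five 6-min intervals, each with N_new/N_window = 0.06:
  # cumulative points (6, 0.06) ... (30, 0.30), slope exactly 0.01/min
  counts <- make_counts(t_end = seq(6, 30, by = 6), n_new = 6, n_start = 100)
  est <- mean_rate(counts, "division")
  expect_equal(est$rate, 0.01)
  expect_equal(est$stderr, 0, tolerance = 1e-12)
  # an event-free series gives exactly zero
  est0 <- mean_rate(make_counts(seq(6, 60, by = 6), n_new = 0), "division")
  expect_equal(est0$rate, 0)
})

test_that("adding non-dividing resident cells strictly dilutes the rate", {
  tab1 <- stationary_table(n = 10, n_frames = 10,
                           birth_frames = c(2, 5, 8))
  tab2 <- stationary_table(n = 15, n_frames = 10,
                           birth_frames = c(2, 5, 8))
  r1 <- mean_rate(frame_counts(tab1), "division")$rate
  r2 <- mean_rate(frame_counts(tab2), "division")$rate
  expect_true(r2 < r1)
  expect_true(r1 > 0)
})

test_that("zero-denominator intervals are skipped with a warning", {
  counts <- make_counts(t_end = seq(6, 36, by = 6), n_new = 1, n_start = 10)
  counts$n_start[3] <- 0
  expect_warning(est <- mean_rate(counts, "division"), "zero")
  expect_equal(est$n_intervals, 5)
  expect_error(suppressWarnings(
    mean_rate(make_counts(seq(6, 18, by = 6), n_new = 1, n_start = 0),
              "division")), "at least 3")
})

test_that("a periodic schedule trims intervals of the incomplete final period", {
  counts <- make_counts(t_end = seq(66, 6 + 60 * 6, by = 6), n_new = 3)
  sched <- make_schedule("IPS", period = 96, acclimation = 60,
                         total_duration = 366)
  est <- mean_rate(counts, "division", schedule = sched)
  # data runs to 366 min; only 3 whole periods fit after acclimation
  expect_equal(est$t1, 60 + 3 * 96)
  expect_equal(est$t0, 60)
  est_free <- mean_rate(counts, "division")
  expect_equal(est_free$t1, max(counts$t_end))
})

test_that("instantaneous rates localize an event burst and vanish elsewhere", {
  n_new <- rep(0, 30)
  n_new[15] <- 10
  counts <- make_counts(t_end = seq(6, 180, by = 6), n_new = n_new)
  ser <- instantaneous_rates(counts, width = 36, step = 6)
  peak_time <- ser$time[which.max(ser$rate)]
  burst_mid <- (counts$t_start[15] + counts$t_end[15]) / 2
  expect_lt(abs(peak_time - burst_mid), 18 + 1e-9)
  far <- abs(ser$time - burst_mid) > 24
  expect_true(all(ser$rate[far] == 0, na.rm = TRUE))
  # an event-free series is identically zero
  ser0 <- instantaneous_rates(make_counts(seq(6, 180, by = 6), n_new = 0),
                              width = 36)
  expect_true(all(ser0$rate == 0, na.rm = TRUE))
  expect_true(any(ser0$truncated))
  expect_error(instantaneous_rates(make_counts(seq(6, 18, 6), n_new = 0),
                                   width = 36), "shorter")
})
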