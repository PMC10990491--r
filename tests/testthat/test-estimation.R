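test_that("the estimator matches the configured rate on a homogeneous simulation", {
  sched <- make_schedule("constant", total_duration = 720, acclimation = 0)
  cfg <- sim_config(initial_cells = 150, division_rate_map = 0.005,
                    division_lag = 0, lysis_slope = 0, seed = 42)
  sim <- simulate_chamber(cfg, sched)
  counts <- frame_counts(sim$table, tracking_window())
  est <- mean_rate(counts, "division")
  oracle <- true_rates(sim$truth, est$t0, est$t1)[["division_rate"]]
  expect_lt(abs(est$rate - oracle) / oracle, 0.15)
  expect_lt(abs(est$rate - 0.005) / 0.005, 0.15)
})

test_that("without window crossings the estimator agrees with the event-log oracle", {
  # window spanning the whole field, immobile cells, no crowding: the two
  # routes count the same events and may differ only through denominator
  # timing
  win <- tracking_window(2048, 2048)
  sched <- make_schedule("constant", total_duration = 600, acclimation = 0)
  cfg <- sim_config(initial_cells = 200, division_rate_map = 0.004,
                    division_lag = 0, lysis_slope = 0, motility_sigma = 0,
                    crowding_capacity = 5000, seed = 13)
  sim <- simulate_chamber(cfg, sched, window = win)
  counts <- frame_counts(sim$table, win)
  expect_equal(sum(counts$n_in) + sum(counts$n_out), 0)
  est <- mean_rate(counts, "division")
  oracle <- true_rates(sim$truth, est$t0, est$t1)[["division_rate"]]
  expect_lt(abs(est$rate - oracle) / oracle, 0.02)
})

test_that("instantaneous rates time-average to the global estimate", {
  sched <- make_schedule("constant", total_duration = 480, acclimation = 0)
  cfg <- sim_config(initial_cells = 200, division_rate_map = 0.005,
                    division_lag = 0, lysis_slope = 0, seed = 14)
  sim <- simulate_chamber(cfg, sched)
  counts <- frame_counts(sim$table, tracking_window())
  ser <- instantaneous_rates(counts, width = 36, step = 6)
  glob <- mean_rate(counts, "division")$rate
  expect_lt(abs(mean(ser$rate[!ser$truncated]) - glob) / glob, 0.10)
})

test_that("shrinking the window by 20% moves estimates less than the replicate CI", {
  sched <- make_schedule("constant", total_duration = 480, acclimation = 0)
  est_with <- function(win) {
    vapply(1:5, function(s) {
      cfg <- sim_config(initial_cells = 150, division_rate_map = 0.005,
                        division_lag = 0, lysis_slope = 0, seed = s)
      sim <- simulate_chamber(cfg, sched)
      mean_rate(frame_counts(sim$table, win), "division")$rate
    }, numeric(1))
  }
  full <- est_with(tracking_window(2048, 1928))
  shrunk <- est_with(tracking_window(2048, round(1928 * 0.8)))
  s <- replicate_summary(full)
  ci_width <- s$ci_high - s$ci_low
  expect_lt(abs(mean(shrunk) - mean(full)), ci_width)
})

test_that("phase folding reindexes a single fov and averages across periods", {
  # two periods with per-interval rates r and 3r at matching phases
  Tp <- 48; dt <- 6
  sched <- make_schedule("IPS", period = Tp, acclimation = 0,
                         total_duration = 2 * Tp)
  n1 <- 2; n2 <- 6  # events per interval in period 1 and 2, N = 100
  counts <- make_counts(t_end = seq(dt, 2 * Tp, by = dt),
                        n_new = rep(c(n1, n2), each = Tp / dt))
  prof <- fold_by_phase(counts, sched)
  r <- n1 / 100 / dt
  expect_equal(prof$bins$mean_rate, rep(2 * r, Tp / dt))
  expect_equal(unname(prof$half_period_means), rep(2 * r, 2))
  # a single period equals the series re-indexed by phase
  sched1 <- make_schedule("IPS", period = Tp, acclimation = 0,
                          total_duration = Tp)
  counts1 <- counts[seq_len(Tp / dt), ]
  class(counts1) <- class(counts)
  prof1 <- fold_by_phase(counts1, sched1)
  expect_equal(prof1$bins$mean_rate, rep(r, Tp / dt))
  expect_equal(prof1$bins$phase_center, seq(3, Tp - 3, by = dt))
})

test_that("estimates survive tracking errors within tolerance", {
  sched <- make_schedule("constant", total_duration = 600, acclimation = 0)
  cfg <- sim_config(initial_cells = 150, division_rate_map = 0.005,
                    death_rate_map = 0.002, division_lag = 0,
                    lysis_slope = 0, seed = 17)
  sim <- simulate_chamber(cfg, sched)
  clean <- frame_counts(sim$table, tracking_window())
  bad <- inject_tracking_errors(sim$table, swap_rate = 0.05,
                                drop_rate = 0.02, frame_drop_rate = 0.02,
                                seed = 18)
  corrupt <- suppressWarnings(frame_counts(bad, tracking_window()))
  for (ev in c("division", "death")) {
    r0 <- mean_rate(clean, ev)$rate
    r1 <- mean_rate(corrupt, ev)$rate
    expect_lt(abs(r1 - r0) / r0, 0.15, label = ev)
  }
})
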