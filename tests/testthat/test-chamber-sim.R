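test_that("null dynamics keep the population constant with no lineage", {
  sched <- make_schedule("constant", total_duration = 120, acclimation = 0)
  cfg <- sim_config(initial_cells = 30, division_rate_map = 0,
                    lysis_slope = 0, motility_sigma = 0, seed = 1)
  sim <- simulate_chamber(cfg, sched)
  per_frame <- table(sim$table$frame)
  expect_true(all(per_frame == 30))
  expect_true(all(is.na(sim$table$parent_id)))
  expect_false(any(sim$table$dead))
  expect_equal(nrow(sim$truth$events), 0)
})

test_that("pure growth matches the branching-process law across seeds", {
  # oracle: discrete Galton-Watson with offspring 1 + Bernoulli(p),
  # p = 1 - exp(-r dt); its mean/variance are closed-form, and its mean
  # is within a few percent of the Yule-process mean N0 * exp(r t)
  r <- 0.006; dt <- 6; dur <- 300; n0 <- 50
  k <- dur / dt
  p <- 1 - exp(-r * dt)
  m <- 1 + p
  gw_mean <- n0 * m^k
  gw_var <- n0 * p * (1 - p) * m^(k - 1) * (m^k - 1) / (m - 1)
  yule_mean <- n0 * exp(r * dur)
  yule_sd <- sqrt(n0 * exp(r * dur) * (exp(r * dur) - 1))
  sched <- make_schedule("constant", total_duration = dur, acclimation = 0)
  finals <- vapply(1:20, function(s) {
    cfg <- sim_config(initial_cells = n0, division_rate_map = r,
                      division_lag = 0, lysis_slope = 0, motility_sigma = 0,
                      crowding_capacity = 10000, seed = s)
    sim <- simulate_chamber(cfg, sched)
    sum(sim$table$frame == max(sim$table$frame))
  }, numeric(1))
  expect_lt(abs(mean(finals) - gw_mean), 3 * sqrt(gw_var / 20))
  expect_lt(abs(mean(finals) - yule_mean), 3 * yule_sd)
})

test_that("lysis clusters within minutes of sorbitol down-shifts", {
  sched <- make_schedule("AS", period = 48, acclimation = 60,
                         total_duration = 60 + 48 * 8)
  cfg <- sim_config(initial_cells = 120, glycerol_kappa = 3, seed = 5)
  sim <- simulate_chamber(cfg, sched)
  ev <- sim$truth$events
  lysis_times <- ev$time[ev$type == "lysis"]
  expect_gt(length(lysis_times), 10)
  tr <- transition_times(sched)
  downshifts <- tr[env_at(sched, pmax(0, tr - 1e-9))$sorbitol >
                     env_at(sched, tr)$sorbitol]
  within12 <- vapply(lysis_times, function(t0) {
    any(t0 - downshifts >= 0 & t0 - downshifts <= 12)
  }, logical(1))
  expect_gte(mean(within12), 0.8)
})

test_that("no lysis slope means no death records at all", {
  sched <- make_schedule("AS", period = 24, total_duration = 300)
  cfg <- sim_config(initial_cells = 50, lysis_slope = 0, seed = 2)
  sim <- simulate_chamber(cfg, sched)
  expect_false(any(sim$table$dead))
  expect_false(any(sim$truth$events$type %in% c("lysis", "death")))
})

test_that("identical config, schedule and seed give identical output", {
  sched <- make_schedule("IPS", period = 24, total_duration = 240)
  cfg <- sim_config(initial_cells = 40, seed = 9)
  a <- simulate_chamber(cfg, sched)
  b <- simulate_chamber(cfg, sched)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$population, b$truth$population)
})

test_that("the IPS/AS death asymmetry emerges from glycerol phasing alone", {
  # same glucose timing, same seed stream; only the sorbitol phase differs
  cfg <- sim_config(initial_cells = 150, seed = 3)
  rates <- vapply(c("IPS", "AS"), function(rg) {
    sched <- make_schedule(rg, period = 24, total_duration = 60 + 24 * 10)
    sim <- simulate_chamber(cfg, sched)
    true_rates(sim$truth, 60, 300)[["death_rate"]]
  }, numeric(1))
  expect_gt(rates[["AS"]], 2 * rates[["IPS"]])
})

test_that("true_rates does direct arithmetic on the event log", {
  truth <- structure(list(
    events = data.frame(time = c(10, 20, 30, 40),
                        type = c("division", "division", "division", "death"),
                        object_id = 1:4, parent_id = NA,
                        in_window = c(TRUE, TRUE, TRUE, FALSE)),
    population = data.frame(frame = 0:9, time = seq(0, 90, by = 10),
                            n_window_living = rep(6, 10)),
    imaging_interval = 10
  ), class = "sim_truth")
  # 3 in-window divisions over 600 cell-minutes -> 0.005 / min
  tr <- true_rates(truth, 0, 100)
  expect_equal(tr[["division_rate"]], 0.005)
  # the death event sits outside the window: death rate 0
  expect_equal(tr[["death_rate"]], 0)
  # no events at all -> (0, 0)
  truth0 <- truth
  truth0$events <- truth$events[0, ]
  expect_equal(unname(true_rates(truth0, 0, 100)), c(0, 0))
  expect_error(true_rates(truth, 50, 50), "empty")
})

test_that("tracking-error injection is the identity at zero rates and deterministic", {
  sim <- random_clean_sim(77)
  expect_identical(inject_tracking_errors(sim$table, 0, 0, 0, seed = 1),
                   sim$table)
  a <- inject_tracking_errors(sim$table, 0.05, 0.02, 0.02, seed = 4)
  b <- inject_tracking_errors(sim$table, 0.05, 0.02, 0.02, seed = 4)
  expect_identical(a, b)
  expect_false(identical(as.data.frame(a), as.data.frame(sim$table)))
  expect_error(inject_tracking_errors(sim$table, swap_rate = 1.2), "0, 1")
})

test_that("frame drops keep original timestamps and open gaps", {
  sim <- random_clean_sim(78)
  out <- inject_tracking_errors(sim$table, frame_drop_rate = 0.2, seed = 6)
  expect_lt(length(unique(out$frame)), length(unique(sim$table$frame)))
  # surviving frames keep their original times
  orig <- unique(as.data.frame(sim$table)[, c("frame", "time")])
  kept <- unique(as.data.frame(out)[, c("frame", "time")])
  merged <- merge(kept, orig, by = "frame")
  expect_equal(merged$time.x, merged$time.y)
  # swaps preserve the positional records, permuting only identities
  sw <- inject_tracking_errors(sim$table, swap_rate = 0.1, seed = 6)
  expect_equal(sort(paste(sw$frame, sw$x, sw$y)),
               sort(paste(sim$table$frame, sim$table$x, sim$table$y)))
  expect_equal(sort(paste(sw$frame, sw$object_id)),
               sort(paste(sim$table$frame, sim$table$object_id)))
})
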