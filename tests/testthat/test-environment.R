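test_that("IPS and AS regimes pair the stresses as defined", {
  ips <- make_schedule("IPS", period = 96, glucose_high = 2,
                       sorbitol_high = 1, acclimation = 60,
                       total_duration = 540)
  as_ <- make_schedule("AS", period = 96, glucose_high = 2,
                       sorbitol_high = 1, acclimation = 60,
                       total_duration = 540)
  # IPS: first half glucose without stress, second half depletion + stress
  e <- env_at(ips, 60 + c(0, 24, 47.9, 48, 90))
  expect_equal(e$glucose, c(2, 2, 2, 0, 0))
  expect_equal(e$sorbitol, c(0, 0, 0, 1, 1))
  # AS: first half glucose WITH stress, second half neither
  e <- env_at(as_, 60 + c(0, 24, 47.9, 48, 90))
  expect_equal(e$glucose, c(2, 2, 2, 0, 0))
  expect_equal(e$sorbitol, c(1, 1, 1, 0, 0))
  # same glucose timing: the two regimes differ only in sorbitol phasing
  tt <- seq(60, 540, by = 3)
  expect_equal(env_at(ips, tt)$glucose, env_at(as_, tt)$glucose)
})

test_that("constant regime and acclimation give the default medium", {
  const <- make_schedule("constant", glucose_high = 2, total_duration = 300)
  e <- env_at(const, c(0, 100, 300))
  expect_true(all(e$glucose == 2) && all(e$sorbitol == 0))
  # any periodic regime is in the default medium during acclimation
  for (rg in c("periodic_osmo", "IPS", "AS")) {
    s <- make_schedule(rg, period = 24, total_duration = 300)
    e <- env_at(s, c(0, 30, 59.9))
    expect_true(all(e$glucose == 2), info = rg)
    expect_true(all(e$sorbitol == 0), info = rg)
  }
})

test_that("sorbitol exposure occupies exactly half of every whole period", {
  for (rg in c("periodic_osmo", "IPS", "AS")) {
    for (Tp in c(12, 24, 96)) {
      s <- make_schedule(rg, period = Tp, acclimation = 60,
                         total_duration = 60 + 4 * Tp)
      tt <- seq(60, 60 + 4 * Tp - 0.5, by = 0.5)  # 4 whole periods
      frac <- mean(env_at(s, tt)$sorbitol > 0)
      expect_equal(frac, 0.5, info = paste(rg, Tp))
    }
  }
})

test_that("env_at is piecewise constant between transitions", {
  s <- make_schedule("AS", period = 48, total_duration = 400)
  tr <- transition_times(s)
  expect_true(all(diff(tr) > 0))
  # sample two times within each constant segment and compare states
  bounds <- c(0, tr, s$total_duration)
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    t1 <- a + (b - a) / 3; t2 <- a + 2 * (b - a) / 3
    e <- env_at(s, c(t1, t2))
    expect_equal(e$glucose[1], e$glucose[2])
    expect_equal(e$sorbitol[1], e$sorbitol[2])
  }
})

test_that("phase_of follows the modular convention with half-open halves", {
  s <- make_schedule("IPS", period = 96, acclimation = 60,
                     total_duration = 600)
  p <- phase_of(s, 60 + c(100, 48, 0))
  expect_equal(p$phase, c(4, 48, 0))
  expect_equal(as.character(p$half), c("first", "second", "first"))
  s24 <- make_schedule("IPS", period = 24, acclimation = 60,
                       total_duration = 300)
  expect_equal(phase_of(s24, 60)$phase, 0)
  expect_error(phase_of(s24, 30), "acclimation")
})

test_that("schedule construction rejects invalid inputs", {
  expect_error(make_schedule("IPS", period = 0, total_duration = 100),
               "positive")
  expect_error(make_schedule("IPS", total_duration = 100), "positive")
  expect_error(make_schedule("nonsense", period = 10), "arg")
  expect_error(make_schedule("constant", total_duration = 30,
                             acclimation = 60), "acclimation")
  s <- make_schedule("constant", total_duration = 100)
  expect_error(env_at(s, 101), "within")
})

test_that("schedules round-trip through the config block", {
  for (s in list(make_schedule("AS", period = 24, glucose_high = 0.1,
                               total_duration = 480),
                 make_schedule("single_pulse", pulse_start = 120,
                               pulse_length = 48, pulse_glucose = 0,
                               total_duration = 480))) {
    s2 <- schedule_from_config(schedule_to_config(s))
    expect_equal(s2, s)
  }
  expect_error(schedule_from_config(list(regime = "AS", period_min = 24,
                                         bogus_key = 1)), "bogus_key")
})
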