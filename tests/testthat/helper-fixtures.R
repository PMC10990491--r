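# Shared fixtures, all built in code.

# A two-frame table realizing every flux category of the conservation
# relation: A stays inside; B exits; C is born inside with parent A;
# D enters.  Window default: x/y in [60, 1988).
two_frame_table <- function(parent_of_c = "A") {
  tracked_table(data.frame(
    fov = "f1",
    frame = c(0, 0, 0, 1, 1, 1, 1),
    time = c(0, 0, 0, 6, 6, 6, 6),
    object_id = c("A", "B", "D", "A", "B", "C", "D"),
    parent_id = c(NA, NA, NA, NA, NA, parent_of_c, NA),
    x = c(500, 70, 40, 500, 50, 510, 65),
    y = c(500, 500, 500, 500, 500, 505, 500),
    size = 25,
    dead = FALSE,
    stringsAsFactors = FALSE
  ))
}

# A stationary population of n cells inside the window across n_frames,
# with optional daughters appearing at given frames (all parented by cell 1).
stationary_table <- function(n = 10, n_frames = 10, dt = 6,
                             birth_frames = integer(0)) {
  recs <- list()
  ids <- paste0("c", seq_len(n))
  for (f in seq_len(n_frames) - 1) {
    recs[[length(recs) + 1]] <- data.frame(
      fov = "f1", frame = f, time = f * dt,
      object_id = ids, parent_id = NA_character_,
      x = 200 + 10 * seq_len(n), y = 300, size = 25, dead = FALSE,
      stringsAsFactors = FALSE
    )
    born <- which(birth_frames <= f)
    if (length(born) > 0) {
      recs[[length(recs) + 1]] <- data.frame(
        fov = "f1", frame = f, time = f * dt,
        object_id = paste0("d", born), parent_id = "c1",
        x = 600 + 10 * born, y = 300, size = 25, dead = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  tracked_table(do.call(rbind, recs))
}

# Minimal frame-counts object for estimator arithmetic tests.
make_counts <- function(t_end, n_new, n_start = 100, dt = 6,
                        n_death = 0) {
  out <- data.frame(
    t_start = t_end - dt, t_end = t_end,
    n_start = n_start, n_end = n_start,
    n_new = n_new, n_in = 0, n_out = 0,
    n_death = n_death, n_anomaly = 0
  )
  class(out) <- c("frame_counts", "data.frame")
  out
}

# Random clean simulation configurations for property tests.
random_clean_sim <- function(seed) {
  set.seed(seed)
  regime <- sample(c("constant", "periodic_osmo", "periodic_glucose",
                     "IPS", "AS"), 1)
  period <- sample(c(24, 48, 96), 1)
  sched <- make_schedule(regime,
                         period = if (regime == "constant") NULL else period,
                         acclimation = sample(c(0, 60), 1),
                         total_duration = sample(c(120, 180, 240), 1))
  cfg <- sim_config(
    initial_cells = sample(20:60, 1),
    division_rate_map = rate_map(
      glucose_no_stress = runif(1, 0, 0.008),
      glucose_stress = runif(1, 0, 0.004),
      starved_no_stress = runif(1, 0, 0.003),
      starved_stress = runif(1, 0, 0.002)
    ),
    death_rate_map = sample(c(0, 0.002), 1),
    lysis_slope = runif(1, 0, 0.3),
    motility_sigma = runif(1, 2, 15),
    crowding_capacity = sample(c(80, 200), 1),
    division_lag = sample(c(0, 12), 1),
    seed = seed
  )
  simulate_chamber(cfg, sched)
}
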