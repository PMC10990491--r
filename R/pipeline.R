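config_schema <- function() {
  list(
    schedule = c("regime", "period_min", "glucose_high_pct",
                 "sorbitol_high_M", "acclimation_min", "duration_min",
                 "pulse_start_min", "pulse_length_min", "pulse_glucose_pct"),
    sim = c("initial_cells", "imaging_interval_min", "frame_size_px",
            "division_rate", "division_rates", "death_rate",
            "division_lag_min", "glycerol_gain", "glycerol_kappa",
            "glycerol_decay", "glycerol_release", "lysis_slope",
            "motility_sigma_px", "crowding_capacity", "advection_step_px",
            "dead_persistence_frames", "nucleus_size_mean_px",
            "nucleus_size_sd_px", "record_states"),
    sim_division_rates = c("glucose_no_stress", "glucose_stress",
                           "starved_no_stress", "starved_stress"),
    reporters = c("hog1_peak", "hog1_adapt_rate_glucose",
                  "hog1_adapt_rate_starved", "hog1_release_rate",
                  "hog1_threshold", "pstl1_txn_rate",
                  "pstl1_maturation_delay", "pstl1_dilution", "noise_cv",
                  "baseline_fluor"),
    estimation = c("frame_size_px", "window_size_px", "denominator",
                   "var_equal", "width_min", "step_min"),
    top = c("schedule", "sim", "reporters", "estimation", "seeds")
  )
}

check_keys <- function(block, known, path) {
  extra <- setdiff(names(block), known)
  if (length(extra) > 0) {
    stopf("unknown configuration key '%s.%s'", path, extra[1])
  }
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration with blocks `schedule` (required), `sim`,
#' `reporters`, `estimation` and `seeds`, validates it against the known
#' schema (unknown keys are rejected, naming the offending key), fills
#' defaults, and resolves the blocks into package objects.
#'
#' @param path YAML file path, or a named list already parsed.
#' @return an object of class `experiment_config` with elements
#'   `schedule` ([make_schedule()]), `sim_base` (argument list for
#'   [sim_config()]), `reporters` ([reporter_params()]), `estimation`
#'   (window and estimator options) and `seeds`.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(raw)) stopf("configuration must be a mapping")
  sch <- config_schema()
  check_keys(raw, sch$top, "config")
  if (is.null(raw$schedule)) stopf("configuration requires a 'schedule' block")
  check_keys(raw$schedule, sch$schedule, "schedule")
  schedule <- schedule_from_config(raw$schedule)

  simb <- raw$sim %||% list()
  check_keys(simb, sch$sim, "sim")
  if (!is.null(simb$division_rates)) {
    check_keys(simb$division_rates, sch$sim_division_rates,
               "sim.division_rates")
  }
  division_map <- if (!is.null(simb$division_rate)) {
    simb$division_rate
  } else if (!is.null(simb$division_rates)) {
    do.call(rate_map, simb$division_rates)
  } else {
    rate_map()
  }
  sim_base <- list(
    initial_cells = simb$initial_cells %||% 150,
    imaging_interval = simb$imaging_interval_min %||% 6,
    frame_size = simb$frame_size_px %||% 2048,
    division_rate_map = division_map,
    death_rate_map = simb$death_rate %||% 0,
    division_lag = simb$division_lag_min %||% 12,
    glycerol_gain = simb$glycerol_gain %||% 0.02,
    glycerol_kappa = simb$glycerol_kappa %||% 2,
    glycerol_decay = simb$glycerol_decay %||% 0.01,
    glycerol_release = simb$glycerol_release %||% 0.5,
    lysis_slope = simb$lysis_slope %||% 0.1,
    motility_sigma = simb$motility_sigma_px %||% 8,
    crowding_capacity = simb$crowding_capacity %||% 800,
    advection_step = simb$advection_step_px %||% 150,
    dead_persistence = simb$dead_persistence_frames %||% 999,
    nucleus_size_mean = simb$nucleus_size_mean_px %||% 25,
    nucleus_size_sd = simb$nucleus_size_sd_px %||% 3,
    record_states = simb$record_states %||% FALSE
  )

  repb <- raw$reporters %||% list()
  check_keys(repb, sch$reporters, "reporters")
  reporters <- do.call(reporter_params, repb)

  estb <- raw$estimation %||% list()
  check_keys(estb, sch$estimation, "estimation")
  estimation <- list(
    window = tracking_window(estb$frame_size_px %||% sim_base$frame_size,
                             estb$window_size_px %||%
                               (sim_base$frame_size - 120)),
    denominator = estb$denominator %||% "start",
    var_equal = estb$var_equal %||% FALSE,
    width = estb$width_min %||% 36,
    step = estb$step_min %||% 6
  )

  structure(
    list(schedule = schedule, sim_base = sim_base, reporters = reporters,
         estimation = estimation,
         seeds = as.integer(raw$seeds %||% 1L),
         raw = raw),
    class = "experiment_config"
  )
}

#' Serialize the resolved configuration of a run
#'
#' Writes the raw configuration block of an [load_config()] object to
#' YAML so a run's output directory carries its exact settings.
#'
#' @param config an `experiment_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' End-to-end parameter-recovery experiment
#'
#' For each seed: simulate a chamber, (optionally) corrupt the tracked
#' table with tracking errors, estimate division and death rates with the
#' Eulerian estimator, and compare them with the simulation's
#' ground-truth event-log rates over the same analysis interval.  The
#' report records, per replicate, true and estimated rates, relative
#' errors, conservation-identity violations and anomaly counts (both of
#' which must be zero on clean tables).
#'
#' @param config an [load_config()] object.
#' @param corrupt optional list with `swap_rate`, `drop_rate`,
#'   `frame_drop_rate` to re-estimate on corrupted tables.
#' @param out_dir optional directory; when given, the per-replicate table,
#'   summary JSON and resolved configuration are written there.
#' @return an object of class `recovery_report`: `results` (one row per
#'   seed) and `summary` (mean absolute relative errors and worst-case
#'   identity violations).
#' @export
run_recovery <- function(config, corrupt = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  est <- config$estimation
  rows <- lapply(seq_along(config$seeds), function(i) {
    seed <- config$seeds[i]
    cfg <- do.call(sim_config, c(config$sim_base,
                                 list(seed = seed,
                                      fov = sprintf("fov%02d", i))))
    sim <- simulate_chamber(cfg, config$schedule, window = est$window)
    counts <- frame_counts(sim$table, est$window)
    div <- mean_rate(counts, "division", schedule = config$schedule,
                     denominator = est$denominator)
    dth <- mean_rate(counts, "death", schedule = config$schedule,
                     denominator = est$denominator)
    tr <- true_rates(sim$truth, div$t0, div$t1)
    row <- data.frame(
      seed = seed,
      true_division = tr[["division_rate"]],
      est_division = div$rate,
      true_death = tr[["death_rate"]],
      est_death = dth$rate,
      identity_violations = sum(check_conservation(counts) != 0),
      anomalies = sum(counts$n_anomaly)
    )
    row$rel_err_division <- if (row$true_division > 0) {
      (row$est_division - row$true_division) / row$true_division
    } else {
      NA_real_
    }
    row$rel_err_death <- if (row$true_death > 0) {
      (row$est_death - row$true_death) / row$true_death
    } else {
      NA_real_
    }
    if (!is.null(corrupt)) {
      bad <- inject_tracking_errors(
        sim$table,
        swap_rate = corrupt$swap_rate %||% 0,
        drop_rate = corrupt$drop_rate %||% 0,
        frame_drop_rate = corrupt$frame_drop_rate %||% 0,
        seed = seed + 10000L
      )
      counts_bad <- frame_counts(bad, est$window)
      row$est_division_corrupt <-
        mean_rate(counts_bad, "division", schedule = config$schedule,
                  denominator = est$denominator)$rate
      row$est_death_corrupt <-
        mean_rate(counts_bad, "death", schedule = config$schedule,
                  denominator = est$denominator)$rate
    }
    row
  })
  results <- do.call(rbind, rows)
  summary <- list(
    n_replicates = nrow(results),
    division_mare = mean(abs(results$rel_err_division), na.rm = TRUE),
    death_mare = if (all(is.na(results$rel_err_death))) NA_real_ else
      mean(abs(results$rel_err_death), na.rm = TRUE),
    max_identity_violations = max(results$identity_violations),
    total_anomalies = sum(results$anomalies)
  )
  if (!is.null(corrupt)) {
    dev <- abs(results$est_division_corrupt - results$est_division) /
      abs(results$est_division)
    summary$corrupt_division_mean_dev <- mean(dev, na.rm = TRUE)
  }
  report <- structure(list(results = results, summary = summary,
                           corrupt = corrupt),
                      class = "recovery_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "recovery_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "recovery_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  report
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat("<recovery_report>", s$n_replicates, "replicate(s)\n")
  cat(sprintf("  division MARE: %.2f%%", 100 * s$division_mare))
  if (!is.na(s$death_mare)) cat(sprintf(" | death MARE: %.2f%%",
                                        100 * s$death_mare))
  cat("\n  identity violations (max):", s$max_identity_violations,
      "| anomalies:", s$total_anomalies, "\n")
  if (!is.null(s$corrupt_division_mean_dev)) {
    cat(sprintf("  corrupted-vs-clean division deviation: %.2f%%\n",
                100 * s$corrupt_division_mean_dev))
  }
  invisible(x)
}

#' Demonstration run: synthetic figures and tables
#'
#' Simulates one chamber per seed under the configured schedule and
#' writes (all clearly labelled as synthetic data): the instantaneous
#' division-rate series, the phase-folded profile (periodic schedules),
#' and population reporter curves, as CSV tables and ggplot figures.
#'
#' @param config an [load_config()] object.
#' @param out_dir output directory.
#' @return invisibly, the list of files written.
#' @export
run_demo <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- config$estimation
  files <- character(0)
  counts_list <- list()
  series_list <- list()
  for (i in seq_along(config$seeds)) {
    cfg <- do.call(sim_config, c(config$sim_base,
                                 list(seed = config$seeds[i],
                                      fov = sprintf("fov%02d", i))))
    sim <- simulate_chamber(cfg, config$schedule, window = est$window)
    counts_list[[i]] <- frame_counts(sim$table, est$window)
    series_list[[i]] <- instantaneous_rates(counts_list[[i]],
                                            width = est$width,
                                            step = est$step)
    if (i == 1) first_sim <- sim
  }
  ser <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    cbind(fov = sprintf("fov%02d", i), as.data.frame(series_list[[i]]))
  }))
  f <- file.path(out_dir, "instantaneous_division_rates_synthetic.csv")
  utils::write.csv(ser, f, row.names = FALSE)
  files <- c(files, f)
  p <- ggplot2::ggplot(ser[!is.na(ser$rate), ],
                       ggplot2::aes(x = time, y = rate, colour = fov)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Instantaneous division rate (synthetic data)",
                  x = "time (min)", y = "division rate (1/min)")
  f <- file.path(out_dir, "instantaneous_division_rates_synthetic.pdf")
  ggplot2::ggsave(f, p, width = 7, height = 4)
  files <- c(files, f)

  if (config$schedule$regime %in% periodic_regimes()) {
    prof <- fold_by_phase(counts_list, config$schedule)
    f <- file.path(out_dir, "phase_profile_synthetic.csv")
    utils::write.csv(prof$bins, f, row.names = FALSE)
    files <- c(files, f)
    p <- ggplot2::ggplot(prof$bins,
                         ggplot2::aes(x = phase_center, y = mean_rate)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = ci95_low, ymax = ci95_high),
                           alpha = 0.3) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::labs(title = sprintf(
        "Phase-folded division rate, %s T=%g min (synthetic data)",
        config$schedule$regime, config$schedule$period),
        x = "phase (min)", y = "division rate (1/min)")
    f <- file.path(out_dir, "phase_profile_synthetic.pdf")
    ggplot2::ggsave(f, p, width = 7, height = 4)
    files <- c(files, f)
  }

  traces <- simulate_reporters(first_sim$truth, config$reporters,
                               config$schedule, seed = config$seeds[1])
  enr <- nuclear_enrichment(traces)
  f <- file.path(out_dir, "nuclear_enrichment_synthetic.csv")
  utils::write.csv(enr$population, f, row.names = FALSE)
  files <- c(files, f)
  p <- ggplot2::ggplot(enr$population, ggplot2::aes(x = time, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci95_low, ymax = ci95_high),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Nuclear enrichment of the translocation reporter (synthetic data)",
                  x = "time (min)", y = "nuclear / whole-cell fluorescence")
  f <- file.path(out_dir, "nuclear_enrichment_synthetic.pdf")
  ggplot2::ggsave(f, p, width = 7, height = 4)
  files <- c(files, f)
  invisible(files)
}
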