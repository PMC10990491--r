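#' Reporter dynamics parameters
#'
#' Parameters of the synthetic nuclear-translocation (Hog1-GFP style) and
#' stress-promoter (P_STL1-mCitrine style) reporter model.  These are
#' configuration values chosen to reproduce qualitative time-scales of
#' osmostress signaling, not fitted estimates.
#'
#' The translocation reporter jumps to `hog1_peak` nuclear enrichment at
#' each sorbitol up-shift and relaxes exponentially toward 1.  While
#' stress persists, the relaxation rate depends on glucose
#' (`hog1_adapt_rate_glucose` with glucose, `hog1_adapt_rate_starved`
#' without: adaptation is much slower when starved).  When stress is
#' released the reporter returns at `hog1_release_rate`.  The promoter
#' reporter integrates transcription gated on (nuclear enrichment above
#' `hog1_threshold` AND glucose present), with a fluorophore maturation
#' delay and first-order dilution.
#'
#' @param hog1_peak enrichment ratio reached at a shock (> 1).
#' @param hog1_adapt_rate_glucose,hog1_adapt_rate_starved relaxation rates
#'   under stress, min^-1; the glucose rate must exceed the starved rate.
#' @param hog1_release_rate relaxation rate after stress release, min^-1.
#' @param hog1_threshold enrichment ratio above which the kinase is
#'   considered nuclear for transcription gating.
#' @param pstl1_txn_rate fold-change units accumulated per minute of
#'   gated transcription.
#' @param pstl1_maturation_delay minutes between transcription and
#'   detectable fluorescence.
#' @param pstl1_dilution first-order dilution of the mature reporter,
#'   min^-1.
#' @param noise_cv coefficient of variation of multiplicative
#'   measurement noise.
#' @param baseline_fluor mean whole-cell fluorescence at baseline (a.u.).
#' @return an object of class `reporter_params`.
#' @export
reporter_params <- function(hog1_peak = 2.5,
                            hog1_adapt_rate_glucose = log(2) / 6,
                            hog1_adapt_rate_starved = log(2) / 45,
                            hog1_release_rate = log(2) / 4,
                            hog1_threshold = 1.3,
                            pstl1_txn_rate = 0.02,
                            pstl1_maturation_delay = 30,
                            pstl1_dilution = 0.005,
                            noise_cv = 0.05,
                            baseline_fluor = 100) {
  if (hog1_peak <= 1) stopf("hog1_peak must exceed 1")
  if (hog1_adapt_rate_glucose <= hog1_adapt_rate_starved) {
    stopf("adaptation with glucose must be faster than when starved")
  }
  if (noise_cv < 0) stopf("noise_cv must be non-negative")
  structure(
    list(hog1_peak = hog1_peak,
         hog1_adapt_rate_glucose = hog1_adapt_rate_glucose,
         hog1_adapt_rate_starved = hog1_adapt_rate_starved,
         hog1_release_rate = hog1_release_rate,
         hog1_threshold = hog1_threshold,
         pstl1_txn_rate = pstl1_txn_rate,
         pstl1_maturation_delay = pstl1_maturation_delay,
         pstl1_dilution = pstl1_dilution,
         noise_cv = noise_cv,
         baseline_fluor = baseline_fluor),
    class = "reporter_params"
  )
}

#' Population-level reporter signal paths
#'
#' Deterministic hidden-state trajectories shared by all cells: nuclear
#' enrichment `h(t)` (jump at each sorbitol up-shift, exponential
#' relaxation at the glucose-dependent rate) and mature promoter-reporter
#' signal `m(t)` (gated, delayed, diluted integration).  Medium switches
#' take effect between frames, so the enrichment jump first appears one
#' frame after the shock and the sampled peak sits at the first
#' post-shock frame.
#'
#' @param schedule an [make_schedule()] schedule.
#' @param params a [reporter_params()].
#' @param dt sampling interval, minutes.
#' @return data.frame with `time`, `enrichment`, `reporter`.
#' @keywords internal
reporter_signal_paths <- function(schedule, params, dt) {
  times <- seq(0, schedule$total_duration, by = dt)
  n <- length(times)
  env <- env_at(schedule, times)
  h <- numeric(n); h[1] <- 1
  m <- numeric(n); m[1] <- 0
  lag_steps <- round(params$pstl1_maturation_delay / dt)
  active <- logical(n)
  for (k in seq_len(n - 1)) {
    sorb <- env$sorbitol[k] > 0
    glu <- env$glucose[k] > 0
    rate <- if (sorb) {
      if (glu) params$hog1_adapt_rate_glucose else params$hog1_adapt_rate_starved
    } else {
      params$hog1_release_rate
    }
    upshift <- sorb && (k == 1 || env$sorbitol[k - 1] == 0)
    from <- if (upshift) params$hog1_peak else h[k]
    h[k + 1] <- 1 + (from - 1) * exp(-rate * dt)
    ## transcription over a step requires the kinase nuclear throughout
    ## the step and glucose present
    active[k] <- h[k] > params$hog1_threshold &&
      h[k + 1] > params$hog1_threshold && glu
    act_delayed <- if (k - lag_steps >= 1) active[k - lag_steps] else FALSE
    m[k + 1] <- max(0, m[k] + dt * params$pstl1_txn_rate * act_delayed -
                      dt * params$pstl1_dilution * m[k])
  }
  data.frame(time = times, enrichment = h, reporter = m)
}

#' Simulate reporter fluorescence traces for tracked cells
#'
#' Builds a per-cell trace table from a chamber simulation's ground
#' truth: whole-cell and nuclear mean fluorescence sampled at the imaging
#' frames, with multiplicative log-normal measurement noise.  Whole-cell
#' fluorescence follows the promoter reporter (`baseline * (1 + m(t))`);
#' nuclear fluorescence is the whole-cell value scaled by the nuclear
#' enrichment `h(t)` (the whole-cell mean includes nuclear pixels).
#'
#' @param truth a `sim_truth` from [simulate_chamber()].
#' @param params a [reporter_params()].
#' @param schedule the same schedule the truth was generated under
#'   (mismatches are an error).
#' @param seed seed for the measurement noise.
#' @return a data.frame of class `cell_traces` with columns `fov`,
#'   `object_id`, `frame`, `time`, `cell_mean_fluor`, `cell_area`,
#'   `nucleus_mean_fluor`, `nucleus_area`.
#' @export
simulate_reporters <- function(truth, params, schedule, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "reporter_params"),
            inherits(schedule, "env_schedule"))
  if (!identical(truth$schedule_config, schedule_to_config(schedule))) {
    stopf("schedule does not match the one the truth was generated under")
  }
  dt <- truth$imaging_interval
  paths <- reporter_signal_paths(schedule, params, dt)
  cells <- truth$cells
  with_seed(seed, {
    recs <- vector("list", nrow(cells))
    sdlog <- sqrt(log(1 + params$noise_cv^2))
    for (i in seq_len(nrow(cells))) {
      t_use <- paths$time[paths$time >= cells$birth_time[i] &
                            paths$time <= cells$end_time[i]]
      if (length(t_use) == 0) next
      kk <- match(t_use, paths$time)
      nt <- length(t_use)
      cell_noise <- exp(stats::rnorm(nt, 0, sdlog))
      nuc_noise <- exp(stats::rnorm(nt, 0, sdlog))
      cell_fluor <- params$baseline_fluor * (1 + paths$reporter[kk]) *
        cell_noise
      recs[[i]] <- data.frame(
        fov = "fov01",
        object_id = cells$object_id[i],
        frame = as.integer(round(t_use / dt)),
        time = t_use,
        cell_mean_fluor = cell_fluor,
        cell_area = 400 + stats::rnorm(nt, 0, 10),
        nucleus_mean_fluor = cell_fluor * paths$enrichment[kk] * nuc_noise,
        nucleus_area = 60 + stats::rnorm(nt, 0, 4),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    rownames(out) <- NULL
    class(out) <- c("cell_traces", "data.frame")
    out
  })
}
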