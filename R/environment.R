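#' Periodic dual-stress environment schedules
#'
#' The experiments alternate two media components: glucose (% wt/vol) and the
#' osmolyte sorbitol (M).  A schedule is piecewise constant in time; in the
#' periodic regimes each half-period lasts exactly `period / 2` minutes and
#' transitions occur only at half-period boundaries.  Every run starts with an
#' acclimation phase (default 60 min) in the default medium (glucose present,
#' no sorbitol) which downstream analyses exclude.
#'
#' Regimes:
#' * `constant`: glucose present, no sorbitol, at all times.
#' * `periodic_osmo`: constant glucose; sorbitol present during the first
#'   half of each period, absent during the second.
#' * `periodic_glucose`: no sorbitol; glucose present during the first half
#'   of each period, absent during the second.
#' * `IPS` (in-phase stresses): first half glucose without sorbitol, second
#'   half glucose depletion with sorbitol, so both stresses co-occur.
#' * `AS` (alternating stresses): first half glucose with sorbitol, second
#'   half neither, so each half-period carries exactly one stress.
#' * `single_pulse`: default medium except for one sorbitol pulse of
#'   `pulse_length` minutes starting at `pulse_start` (absolute time);
#'   glucose during the pulse is `pulse_glucose` (default `glucose_high`).
#'
#' Phase-0 convention: after acclimation, IPS starts with its stress-free
#' half and AS starts with its glucose+sorbitol half, so IPS and AS share
#' identical glucose timing and differ only in the phasing of sorbitol.
#' All segments are half-open `[start, end)`: the state at a transition
#' instant is the new state.
#'
#' @param regime one of `"constant"`, `"periodic_osmo"`, `"periodic_glucose"`,
#'   `"IPS"`, `"AS"`, `"single_pulse"`.
#' @param period fluctuation period T in minutes (required, > 0, for the
#'   periodic regimes).
#' @param glucose_high glucose concentration of the rich state (% wt/vol).
#' @param sorbitol_high sorbitol concentration of the stress state (M).
#' @param acclimation initial acclimation duration in minutes.
#' @param total_duration total schedule duration in minutes.
#' @param pulse_start,pulse_length pulse timing in minutes
#'   (`single_pulse` only; `pulse_start` is absolute time).
#' @param pulse_glucose glucose concentration during the pulse
#'   (`single_pulse` only; defaults to `glucose_high`).
#' @return an object of class `env_schedule`.
#' @examples
#' sched <- make_schedule("IPS", period = 96, total_duration = 540)
#' env_at(sched, c(30, 84, 132))
#' @export
make_schedule <- function(regime = c("constant", "periodic_osmo",
                                     "periodic_glucose", "IPS", "AS",
                                     "single_pulse"),
                          period = NULL,
                          glucose_high = 2,
                          sorbitol_high = 1,
                          acclimation = 60,
                          total_duration = 720,
                          pulse_start = NULL,
                          pulse_length = NULL,
                          pulse_glucose = NULL) {
  regime <- match.arg(regime)
  if (glucose_high < 0 || sorbitol_high < 0) {
    stopf("concentrations must be non-negative")
  }
  if (acclimation < 0) stopf("acclimation must be non-negative")
  if (total_duration < acclimation) {
    stopf("total_duration (%g) must be at least the acclimation time (%g)",
          total_duration, acclimation)
  }
  if (regime %in% periodic_regimes()) {
    if (is.null(period) || !is.finite(period) || period <= 0) {
      stopf("regime '%s' requires a positive fluctuation period", regime)
    }
  } else {
    period <- NA_real_
  }
  if (identical(regime, "single_pulse")) {
    if (is.null(pulse_start) || is.null(pulse_length) ||
        pulse_start < 0 || pulse_length <= 0) {
      stopf("single_pulse requires pulse_start >= 0 and pulse_length > 0")
    }
    pulse_glucose <- pulse_glucose %||% glucose_high
  } else {
    pulse_start <- NA_real_
    pulse_length <- NA_real_
    pulse_glucose <- NA_real_
  }
  structure(
    list(regime = regime, period = period,
         glucose_high = glucose_high, sorbitol_high = sorbitol_high,
         acclimation = acclimation, total_duration = total_duration,
         pulse_start = pulse_start, pulse_length = pulse_length,
         pulse_glucose = pulse_glucose),
    class = "env_schedule"
  )
}

periodic_regimes <- function() c("periodic_osmo", "periodic_glucose",
                                 "IPS", "AS")

#' @export
print.env_schedule <- function(x, ...) {
  cat("<env_schedule>", x$regime, "\n")
  if (x$regime %in% periodic_regimes()) {
    cat("  period:", x$period, "min (half-period", x$period / 2, "min)\n")
  }
  if (identical(x$regime, "single_pulse")) {
    cat("  pulse: [", x$pulse_start, ",", x$pulse_start + x$pulse_length,
        ") min\n")
  }
  cat("  glucose high:", x$glucose_high, "% | sorbitol high:",
      x$sorbitol_high, "M\n")
  cat("  acclimation:", x$acclimation, "min | total:", x$total_duration,
      "min\n")
  invisible(x)
}

#' Evaluate an environment schedule at given times
#'
#' Returns the piecewise-constant state at each time.  Segments are
#' half-open, so the state at a transition instant is the new state.
#' During acclimation the state is the default medium
#' (`glucose_high`, no sorbitol).
#'
#' @param schedule an [make_schedule()] object.
#' @param t numeric vector of times in minutes, within
#'   `[0, total_duration]`.
#' @return a data.frame with columns `time`, `glucose`, `sorbitol`.
#' @export
env_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "env_schedule"))
  if (any(t < 0 | t > schedule$total_duration)) {
    stopf("t must lie within [0, %g]", schedule$total_duration)
  }
  g <- rep(schedule$glucose_high, length(t))
  s <- rep(0, length(t))
  post <- t >= schedule$acclimation
  if (any(post)) {
    tau <- t[post] - schedule$acclimation
    gl <- g[post]
    so <- s[post]
    switch(schedule$regime,
      constant = NULL,
      periodic_osmo = {
        first <- (tau %% schedule$period) < schedule$period / 2
        so[first] <- schedule$sorbitol_high
      },
      periodic_glucose = {
        first <- (tau %% schedule$period) < schedule$period / 2
        gl[!first] <- 0
      },
      IPS = {
        first <- (tau %% schedule$period) < schedule$period / 2
        gl[!first] <- 0
        so[!first] <- schedule$sorbitol_high
      },
      AS = {
        first <- (tau %% schedule$period) < schedule$period / 2
        so[first] <- schedule$sorbitol_high
        gl[!first] <- 0
      },
      single_pulse = {
        inp <- t[post] >= schedule$pulse_start &
          t[post] < schedule$pulse_start + schedule$pulse_length
        so[inp] <- schedule$sorbitol_high
        gl[inp] <- schedule$pulse_glucose
      }
    )
    g[post] <- gl
    s[post] <- so
  }
  data.frame(time = t, glucose = g, sorbitol = s)
}

#' Phase of a time point within the fluctuation period
#'
#' The phase clock starts at 0 at the end of acclimation:
#' `phase = (t - acclimation) mod T`.  The first half-period covers phases
#' `[0, T/2)` (half-open).
#'
#' @param schedule a periodic [make_schedule()] object.
#' @param t times in minutes, at or after the end of acclimation.
#' @return a data.frame with columns `time`, `phase` (minutes in `[0, T)`)
#'   and `half` (factor, `"first"` or `"second"`).
#' @export
phase_of <- function(schedule, t) {
  stopifnot(inherits(schedule, "env_schedule"))
  if (!schedule$regime %in% periodic_regimes()) {
    stopf("phase_of requires a periodic schedule (got '%s')", schedule$regime)
  }
  if (any(t < schedule$acclimation)) {
    stopf("t must be at or after the end of acclimation (%g min)",
          schedule$acclimation)
  }
  phase <- (t - schedule$acclimation) %% schedule$period
  half <- factor(ifelse(phase < schedule$period / 2, "first", "second"),
                 levels = c("first", "second"))
  data.frame(time = t, phase = phase, half = half)
}

#' Times at which the environment state changes
#'
#' @param schedule an [make_schedule()] object.
#' @return numeric vector of transition times (minutes) in
#'   `(0, total_duration)`, i.e. instants at which the state differs from
#'   the state immediately before.
#' @export
transition_times <- function(schedule) {
  stopifnot(inherits(schedule, "env_schedule"))
  cand <- schedule$acclimation
  if (schedule$regime %in% periodic_regimes()) {
    half <- schedule$period / 2
    k <- seq(half, schedule$total_duration - schedule$acclimation, by = half)
    cand <- c(cand, schedule$acclimation + k)
  } else if (identical(schedule$regime, "single_pulse")) {
    cand <- c(cand, schedule$pulse_start,
              schedule$pulse_start + schedule$pulse_length)
  }
  cand <- sort(unique(cand[cand > 0 & cand < schedule$total_duration]))
  if (length(cand) == 0) return(numeric(0))
  eps <- 1e-9
  before <- env_at(schedule, pmax(0, cand - eps))
  after <- env_at(schedule, cand)
  changed <- before$glucose != after$glucose | before$sorbitol != after$sorbitol
  cand[changed]
}

#' Serialize a schedule to a plain configuration list
#'
#' The block uses explicit-unit key names so it can live inside a YAML or
#' JSON experiment configuration.
#'
#' @param schedule an [make_schedule()] object.
#' @return a named list.
#' @export
schedule_to_config <- function(schedule) {
  stopifnot(inherits(schedule, "env_schedule"))
  out <- list(
    regime = schedule$regime,
    period_min = schedule$period,
    glucose_high_pct = schedule$glucose_high,
    sorbitol_high_M = schedule$sorbitol_high,
    acclimation_min = schedule$acclimation,
    duration_min = schedule$total_duration
  )
  if (identical(schedule$regime, "single_pulse")) {
    out$pulse_start_min <- schedule$pulse_start
    out$pulse_length_min <- schedule$pulse_length
    out$pulse_glucose_pct <- schedule$pulse_glucose
  }
  out[!vapply(out, function(v) length(v) == 1 && is.na(v), logical(1))]
}

#' Build a schedule from a configuration block
#'
#' Inverse of [schedule_to_config()].  Unknown keys are rejected.
#'
#' @param config a named list as produced by [schedule_to_config()].
#' @return an `env_schedule`.
#' @export
schedule_from_config <- function(config) {
  known <- c("regime", "period_min", "glucose_high_pct", "sorbitol_high_M",
             "acclimation_min", "duration_min", "pulse_start_min",
             "pulse_length_min", "pulse_glucose_pct")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stopf("unknown schedule key(s): %s", paste(extra, collapse = ", "))
  }
  if (is.null(config$regime)) stopf("schedule block requires a 'regime'")
  make_schedule(
    regime = config$regime,
    period = config$period_min,
    glucose_high = config$glucose_high_pct %||% 2,
    sorbitol_high = config$sorbitol_high_M %||% 1,
    acclimation = config$acclimation_min %||% 60,
    total_duration = config$duration_min %||% 720,
    pulse_start = config$pulse_start_min,
    pulse_length = config$pulse_length_min,
    pulse_glucose = config$pulse_glucose_pct
  )
}
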