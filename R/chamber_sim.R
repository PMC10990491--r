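#' Environment-dependent per-capita rate map
#'
#' Division (and death) rates in the simulator depend on which of the two
#' stresses are present.  This factory builds a vectorized function of
#' `(glucose, sorbitol)` from the four presence/absence combinations.
#' The defaults echo the magnitudes measured for wild-type cells: about
#' 0.0066 divisions/min in rich medium, strongly reduced under glucose
#' depletion and/or 1 M sorbitol.
#'
#' @param glucose_no_stress rate with glucose, no sorbitol (min^-1).
#' @param glucose_stress rate with glucose and sorbitol.
#' @param starved_no_stress rate without glucose or sorbitol.
#' @param starved_stress rate without glucose, with sorbitol.
#' @return a function `(glucose, sorbitol) -> rate` (min^-1).
#' @export
rate_map <- function(glucose_no_stress = 0.0066,
                     glucose_stress = 0.0017,
                     starved_no_stress = 0.0019,
                     starved_stress = 0.0013) {
  rates <- c(glucose_no_stress, glucose_stress,
             starved_no_stress, starved_stress)
  if (any(rates < 0)) stopf("rates must be non-negative")
  function(glucose, sorbitol) {
    ifelse(glucose > 0,
           ifelse(sorbitol > 0, glucose_stress, glucose_no_stress),
           ifelse(sorbitol > 0, starved_stress, starved_no_stress))
  }
}

as_rate_map <- function(x, what = "rate map") {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1) {
    if (x < 0) stopf("%s must be non-negative", what)
    force(x)
    return(function(glucose, sorbitol) rep(x, length(glucose)))
  }
  stopf("%s must be a function(glucose, sorbitol) or a single number", what)
}

#' Simulator configuration
#'
#' Parameters of the agent-based growth-chamber model.  Cells live in a
#' square field of `frame_size` pixels, divide as Bernoulli events with
#' per-frame probability `1 - exp(-r dt)` where `r` is the
#' environment-dependent rate evaluated `division_lag` minutes in the
#' past, accumulate glycerol while sorbitol is present (faster when
#' glucose is also present, factor `1 + glycerol_kappa`), and may lyse at
#' each sorbitol down-shift with probability `min(1, lysis_slope * g)`.
#' Surviving cells release a fraction `glycerol_release` of their glycerol
#' at the down-shift.  A baseline per-capita death rate (`death_rate_map`)
#' supports constant-mortality scenarios without osmotic shifts.  Above
#' `crowding_capacity` living cells, the cells nearest the field edge are
#' advected outward, producing the boundary outflow the Eulerian
#' estimator must absorb.  Dead nuclei remain detectable and motionless
#' for `dead_persistence` frames.
#'
#' @param initial_cells starting number of cells.
#' @param imaging_interval minutes between frames.
#' @param frame_size field-of-view side, pixels.
#' @param division_rate_map function `(glucose, sorbitol) -> min^-1`, or a
#'   single number for a constant rate.  See [rate_map()].
#' @param death_rate_map baseline per-capita death rate map (same forms).
#' @param division_lag minutes between an environment transition and the
#'   division rate taking effect.
#' @param glycerol_gain glycerol units accumulated per minute while
#'   sorbitol is present.
#' @param glycerol_kappa multiplicative boost of glycerol gain when
#'   glucose is present during stress (> 0 makes the in-phase /
#'   alternating asymmetry emergent).
#' @param glycerol_decay first-order glycerol decay, min^-1.
#' @param glycerol_release fraction of glycerol released by survivors at a
#'   sorbitol down-shift.
#' @param lysis_slope lysis probability per unit glycerol at each
#'   down-shift.
#' @param motility_sigma random-walk step s.d., pixels per frame.
#' @param crowding_capacity maximum living cells before edge-directed
#'   advection.
#' @param advection_step outward displacement per frame for advected
#'   cells, pixels.
#' @param dead_persistence frames a dead nucleus remains detectable.
#' @param nucleus_size_mean,nucleus_size_sd nucleus area distribution
#'   (pixels).
#' @param seed integer seed; identical `(config, schedule, seed)` give
#'   byte-identical output.
#' @param record_states keep per-frame per-cell glycerol in the truth
#'   object.
#' @param fov field-of-view label written to the emitted table.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(initial_cells = 150,
                       imaging_interval = 6,
                       frame_size = 2048,
                       division_rate_map = rate_map(),
                       death_rate_map = 0,
                       division_lag = 12,
                       glycerol_gain = 0.02,
                       glycerol_kappa = 2,
                       glycerol_decay = 0.01,
                       glycerol_release = 0.5,
                       lysis_slope = 0.1,
                       motility_sigma = 8,
                       crowding_capacity = 800,
                       advection_step = 150,
                       dead_persistence = 999,
                       nucleus_size_mean = 25,
                       nucleus_size_sd = 3,
                       seed = 1,
                       record_states = FALSE,
                       fov = "fov01") {
  if (initial_cells < 1) stopf("initial_cells must be >= 1")
  if (imaging_interval <= 0) stopf("imaging_interval must be > 0")
  if (crowding_capacity < initial_cells) {
    stopf("crowding_capacity (%d) below initial_cells (%d)",
          crowding_capacity, initial_cells)
  }
  nonneg <- c(division_lag = division_lag, glycerol_gain = glycerol_gain,
              glycerol_kappa = glycerol_kappa, glycerol_decay = glycerol_decay,
              lysis_slope = lysis_slope, motility_sigma = motility_sigma,
              dead_persistence = dead_persistence)
  if (any(nonneg < 0)) {
    stopf("negative parameter: %s",
          paste(names(nonneg)[nonneg < 0], collapse = ", "))
  }
  if (glycerol_release < 0 || glycerol_release > 1) {
    stopf("glycerol_release must lie in [0, 1]")
  }
  structure(
    list(initial_cells = as.integer(initial_cells),
         imaging_interval = imaging_interval,
         frame_size = frame_size,
         division_rate_map = as_rate_map(division_rate_map, "division_rate_map"),
         death_rate_map = as_rate_map(death_rate_map, "death_rate_map"),
         division_lag = division_lag,
         glycerol_gain = glycerol_gain,
         glycerol_kappa = glycerol_kappa,
         glycerol_decay = glycerol_decay,
         glycerol_release = glycerol_release,
         lysis_slope = lysis_slope,
         motility_sigma = motility_sigma,
         crowding_capacity = as.integer(crowding_capacity),
         advection_step = advection_step,
         dead_persistence = as.integer(dead_persistence),
         nucleus_size_mean = nucleus_size_mean,
         nucleus_size_sd = nucleus_size_sd,
         seed = as.integer(seed),
         record_states = isTRUE(record_states),
         fov = fov),
    class = "sim_config"
  )
}

#' Simulate a microfluidic growth chamber
#'
#' Agent-based generator of tracked-nuclei tables with the statistical
#' structure the Eulerian rate analysis assumes: exponential per-capita
#' division with an environment-dependent (and lagged) rate, lysis
#' clustered at hypo-osmotic down-shifts in proportion to accumulated
#' glycerol, optional baseline mortality, boundary crossings of the
#' tracking window through cell motility and crowding-driven outflow, and
#' dead nuclei that persist motionless in the field.
#'
#' @param config a [sim_config()].
#' @param schedule an [make_schedule()] environment schedule.
#' @param window the [tracking_window()] used for the ground-truth
#'   bookkeeping (event in-window flags, per-frame window population).
#' @return a list with elements `table` (a [tracked_table()]) and `truth`
#'   (class `sim_truth`: `$events` with columns `time, type, object_id,
#'   parent_id, in_window`; `$population` with per-frame living counts in
#'   the window; `$cells` roster with birth/end times; optionally
#'   `$states` with per-frame glycerol).
#' @export
simulate_chamber <- function(config, schedule,
                             window = tracking_window(config$frame_size,
                                                      config$frame_size - 120)) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "env_schedule"))
  dt <- config$imaging_interval
  if (schedule$total_duration < dt) {
    stopf("schedule duration shorter than one imaging interval")
  }
  n_frames <- floor(schedule$total_duration / dt) + 1
  times <- (seq_len(n_frames) - 1) * dt
  fs <- config$frame_size

  with_seed(config$seed, {
    n0 <- config$initial_cells
    ## cell state vectors (grow as cells are born)
    id <- seq_len(n0)
    parent <- rep(NA_integer_, n0)
    x <- stats::runif(n0, 20, fs - 20)
    y <- stats::runif(n0, 20, fs - 20)
    g <- rep(0, n0)
    size <- pmax(5, stats::rnorm(n0, config$nucleus_size_mean,
                                 config$nucleus_size_sd))
    birth <- rep(0, n0)
    alive <- rep(TRUE, n0)
    death_frame <- rep(NA_integer_, n0)
    end_reason <- rep(NA_character_, n0)
    removed <- rep(FALSE, n0)
    ## window status at each cell's most recent emission: a cell may only
    ## be retired from the field after it has been recorded outside the
    ## window once, so every window exit is observable in the table
    last_outside <- rep(FALSE, n0)
    next_id <- n0 + 1L

    rows <- vector("list", n_frames)
    states <- if (config$record_states) vector("list", n_frames) else NULL
    ev_time <- numeric(0); ev_type <- character(0)
    ev_id <- integer(0); ev_parent <- integer(0); ev_inwin <- logical(0)
    pop <- integer(n_frames)

    log_events <- function(time, type, ids, parents, inwin) {
      ev_time <<- c(ev_time, rep(time, length(ids)))
      ev_type <<- c(ev_type, rep(type, length(ids)))
      ev_id <<- c(ev_id, ids)
      ev_parent <<- c(ev_parent, parents)
      ev_inwin <<- c(ev_inwin, inwin)
    }

    for (k in seq_len(n_frames)) {
      tau <- times[k]
      fr <- k - 1L

      ## retire cells that left the window and reached the field edge
      ## (only after an out-of-window position was recorded), and dead
      ## nuclei past their persistence, BEFORE emitting this frame
      gone <- !removed & ((alive & last_outside &
                             !in_window(x, y, window) &
                             (pmin(x, y) < 12 | pmax(x, y) > fs - 12)) |
                            (!alive & (fr - death_frame) > config$dead_persistence))
      if (any(gone)) {
        removed[gone] <- TRUE
        left <- gone & alive
        if (any(left)) {
          alive[left] <- FALSE
          end_reason[left] <- "left_field"
          death_frame[left] <- NA_integer_
          ## record as definitively gone: mark an artificial end time
          ev0 <- which(left)
          log_events(tau, "field_exit", id[ev0], parent[ev0],
                     rep(FALSE, length(ev0)))
        }
      }

      present <- !removed & (alive | (!alive & !is.na(death_frame) &
                                        (fr - death_frame) <= config$dead_persistence))
      idx <- which(present)
      rows[[k]] <- list(
        frame = rep(fr, length(idx)), time = rep(tau, length(idx)),
        object_id = id[idx], parent_id = parent[idx],
        x = x[idx], y = y[idx], size = size[idx],
        dead = !alive[idx] & !is.na(death_frame[idx])
      )
      last_outside[idx] <- !in_window(x[idx], y[idx], window)
      if (config$record_states) {
        liv <- which(alive & !removed)
        states[[k]] <- list(frame = rep(fr, length(liv)),
                            time = rep(tau, length(liv)),
                            object_id = id[liv], glycerol = g[liv])
      }
      pop[k] <- sum(alive[idx] & in_window(x[idx], y[idx], window))

      if (k == n_frames) break
      tau_next <- times[k + 1]
      env_now <- env_at(schedule, tau)
      env_next <- env_at(schedule, tau_next)
      env_lag <- env_at(schedule, max(0, tau - config$division_lag))
      living <- which(alive & !removed)

      ## division (Bernoulli per living cell, lagged environment rate)
      r_div <- config$division_rate_map(env_lag$glucose, env_lag$sorbitol)[1]
      p_div <- 1 - exp(-r_div * dt)
      dividing <- living[stats::runif(length(living)) < p_div]
      if (length(dividing) > 0) {
        nd <- length(dividing)
        ang <- stats::runif(nd, 0, 2 * pi)
        rad <- stats::runif(nd, 8, 18)
        dx <- x[dividing] + rad * cos(ang)
        dy <- y[dividing] + rad * sin(ang)
        dx <- pmin(pmax(dx, 1), fs - 1)
        dy <- pmin(pmax(dy, 1), fs - 1)
        new_ids <- seq(next_id, length.out = nd)
        next_id <- next_id + nd
        id <- c(id, new_ids)
        parent <- c(parent, id[dividing])
        x <- c(x, dx); y <- c(y, dy)
        g <- c(g, g[dividing])
        size <- c(size, pmax(5, stats::rnorm(nd, config$nucleus_size_mean,
                                             config$nucleus_size_sd)))
        birth <- c(birth, rep(tau_next, nd))
        alive <- c(alive, rep(TRUE, nd))
        death_frame <- c(death_frame, rep(NA_integer_, nd))
        end_reason <- c(end_reason, rep(NA_character_, nd))
        removed <- c(removed, rep(FALSE, nd))
        last_outside <- c(last_outside, rep(FALSE, nd))
        log_events(tau_next, "division", new_ids, id[dividing],
                   in_window(x[dividing], y[dividing], window))
      }

      ## baseline mortality
      r_death <- config$death_rate_map(env_now$glucose, env_now$sorbitol)[1]
      dying <- integer(0)
      if (r_death > 0) {
        p_death <- 1 - exp(-r_death * dt)
        dying <- living[stats::runif(length(living)) < p_death]
        if (length(dying) > 0) {
          alive[dying] <- FALSE
          death_frame[dying] <- fr + 1L
          end_reason[dying] <- "death"
          log_events(tau_next, "death", id[dying], parent[dying],
                     in_window(x[dying], y[dying], window))
        }
      }

      ## glycerol dynamics over (tau, tau_next)
      still <- which(alive & !removed)
      if (env_now$sorbitol > 0) {
        gain <- config$glycerol_gain *
          (1 + config$glycerol_kappa * (env_now$glucose > 0))
        g[still] <- g[still] + dt * gain
      }
      g[still] <- pmax(0, g[still] - dt * config$glycerol_decay * g[still])

      ## lysis at a hypo-osmotic down-shift
      if (env_now$sorbitol > 0 && env_next$sorbitol == 0 &&
          config$lysis_slope > 0) {
        p_lys <- pmin(1, config$lysis_slope * g[still])
        lysing <- still[stats::runif(length(still)) < p_lys]
        if (length(lysing) > 0) {
          alive[lysing] <- FALSE
          death_frame[lysing] <- fr + 1L
          end_reason[lysing] <- "lysis"
          log_events(tau_next, "lysis", id[lysing], parent[lysing],
                     in_window(x[lysing], y[lysing], window))
        }
        survivors <- setdiff(still, lysing)
        g[survivors] <- g[survivors] * (1 - config$glycerol_release)
      } else if (env_now$sorbitol > 0 && env_next$sorbitol == 0) {
        g[still] <- g[still] * (1 - config$glycerol_release)
      }

      ## motility: reflected random walk of living, non-new cells
      movers <- which(alive & !removed & birth < tau_next)
      if (length(movers) > 0 && config$motility_sigma > 0) {
        was_in <- in_window(x[movers], y[movers], window)
        x[movers] <- reflect(x[movers] +
                               stats::rnorm(length(movers), 0,
                                            config$motility_sigma), fs)
        y[movers] <- reflect(y[movers] +
                               stats::rnorm(length(movers), 0,
                                            config$motility_sigma), fs)

        ## crowding: advect the cells nearest the field edge outward
        n_alive <- sum(alive & !removed)
        excess <- n_alive - config$crowding_capacity
        if (excess > 0) {
          cand <- which(alive & !removed)
          edge_d <- pmin(x[cand], y[cand], fs - x[cand], fs - y[cand])
          adv <- cand[order(edge_d)[seq_len(min(excess, length(cand)))]]
          for (i in adv) {
            dists <- c(x[i], fs - x[i], y[i], fs - y[i])
            side <- which.min(dists)
            ## clamp at 8 px from the edge: an advected cell is always
            ## recorded in the margin (outside the window, inside the
            ## field) at least once before it can be retired, so its
            ## window exit is an observable crossing
            step <- config$advection_step
            if (side == 1) x[i] <- max(8, x[i] - step)
            if (side == 2) x[i] <- min(fs - 8, x[i] + step)
            if (side == 3) y[i] <- max(8, y[i] - step)
            if (side == 4) y[i] <- min(fs - 8, y[i] + step)
          }
        }

        now_in <- in_window(x[movers], y[movers], window)
        cross_out <- movers[was_in & !now_in]
        cross_in <- movers[!was_in & now_in]
        if (length(cross_out) > 0) {
          log_events(tau_next, "window_exit", id[cross_out],
                     parent[cross_out], rep(FALSE, length(cross_out)))
        }
        if (length(cross_in) > 0) {
          log_events(tau_next, "window_entry", id[cross_in],
                     parent[cross_in], rep(TRUE, length(cross_in)))
        }
      }
    }

    tab <- data.frame(
      fov = config$fov,
      frame = unlist(lapply(rows, `[[`, "frame")),
      time = unlist(lapply(rows, `[[`, "time")),
      object_id = unlist(lapply(rows, `[[`, "object_id")),
      parent_id = unlist(lapply(rows, `[[`, "parent_id")),
      x = unlist(lapply(rows, `[[`, "x")),
      y = unlist(lapply(rows, `[[`, "y")),
      size = unlist(lapply(rows, `[[`, "size")),
      dead = unlist(lapply(rows, `[[`, "dead")),
      stringsAsFactors = FALSE
    )
    tab <- tracked_table(tab)

    events <- data.frame(time = ev_time, type = ev_type, object_id = ev_id,
                         parent_id = ev_parent, in_window = ev_inwin,
                         stringsAsFactors = FALSE)
    cells <- data.frame(
      object_id = id, parent_id = parent, birth_time = birth,
      end_time = ifelse(is.na(death_frame),
                        schedule$total_duration, death_frame * dt),
      end_reason = ifelse(is.na(end_reason), "alive_at_end", end_reason),
      stringsAsFactors = FALSE
    )
    truth <- structure(
      list(events = events,
           population = data.frame(frame = seq_len(n_frames) - 1L,
                                   time = times, n_window_living = pop),
           cells = cells,
           window = window,
           imaging_interval = dt,
           schedule_config = schedule_to_config(schedule),
           seed = config$seed),
      class = "sim_truth"
    )
    if (config$record_states) {
      truth$states <- data.frame(
        frame = unlist(lapply(states, `[[`, "frame")),
        time = unlist(lapply(states, `[[`, "time")),
        object_id = unlist(lapply(states, `[[`, "object_id")),
        glycerol = unlist(lapply(states, `[[`, "glycerol"))
      )
    }
    list(table = tab, truth = truth)
  })
}

reflect <- function(v, upper) {
  v <- abs(v)
  over <- v > upper
  v[over] <- 2 * upper - v[over]
  pmin(pmax(v, 0), upper)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", nrow(x$cells), "cells,",
      nrow(x$events), "events over",
      max(x$population$time), "min\n")
  tt <- table(x$events$type)
  if (length(tt) > 0) {
    cat(" ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ground-truth per-capita rates from a simulation event log
#'
#' The oracle against which the Eulerian estimator is validated:
#' `division_rate` is the number of division events among window-resident
#' cells in `(t0, t1]` divided by the total living-cell minutes spent in
#' the window over `[t0, t1]`; the death rate counts lysis and baseline
#' death events analogously.
#'
#' @param truth a `sim_truth` from [simulate_chamber()].
#' @param t0,t1 interval bounds in minutes.
#' @return named numeric vector `c(division_rate, death_rate)` in min^-1.
#' @export
true_rates <- function(truth, t0, t1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (t1 <= t0) stopf("empty interval [%g, %g]", t0, t1)
  pop <- truth$population
  dt <- truth$imaging_interval
  use <- pop$time >= t0 & (pop$time + dt) <= t1
  cell_minutes <- sum(pop$n_window_living[use]) * dt
  if (cell_minutes <= 0) stopf("no living cell time in [%g, %g]", t0, t1)
  ev <- truth$events
  ev <- ev[ev$time > t0 & ev$time <= t1 & ev$in_window, , drop = FALSE]
  n_div <- sum(ev$type == "division")
  n_death <- sum(ev$type %in% c("lysis", "death"))
  c(division_rate = n_div / cell_minutes,
    death_rate = n_death / cell_minutes)
}

#' Inject tracking errors into a tracked table
#'
#' Stress-test harness for the estimator's robustness.  Three independent
#' corruption channels, each deterministic for a given `seed`:
#' * identity swaps: each record is selected with probability
#'   `swap_rate`; a selected record exchanges its `(object_id, parent_id)`
#'   labels with the spatially nearest other record in the same frame.
#' * detection drops: each record is deleted with probability `drop_rate`.
#' * frame drops: each whole frame is removed with probability
#'   `frame_drop_rate` (emulating out-of-focus exclusions).  Surviving
#'   frames keep their original timestamps.
#'
#' @param table a [tracked_table()].
#' @param swap_rate,drop_rate,frame_drop_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return the corrupted table (validation relaxed: corrupted tables may
#'   violate lineage and death-monotonicity invariants).
#' @export
inject_tracking_errors <- function(table, swap_rate = 0, drop_rate = 0,
                                   frame_drop_rate = 0, seed = 1) {
  stopifnot(inherits(table, "tracked_table"))
  rates <- c(swap_rate, drop_rate, frame_drop_rate)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  if (all(rates == 0)) return(table)
  df <- as.data.frame(table)
  with_seed(seed, {
    ## identity swaps within frames
    if (swap_rate > 0 && nrow(df) > 1) {
      oid <- df$object_id
      pid <- df$parent_id
      xx <- df$x
      yy <- df$y
      by_frame <- split(seq_len(nrow(df)), paste(df$fov, df$frame,
                                                 sep = "\r"))
      mark <- stats::runif(nrow(df)) < swap_rate
      for (rows in by_frame) {
        if (length(rows) < 2) next
        for (r in rows[mark[rows]]) {
          others <- rows[rows != r]
          d2 <- (xx[others] - xx[r])^2 + (yy[others] - yy[r])^2
          s <- others[which.min(d2)]
          tmp_id <- oid[r]; tmp_par <- pid[r]
          oid[r] <- oid[s]; pid[r] <- pid[s]
          oid[s] <- tmp_id; pid[s] <- tmp_par
        }
      }
      df$object_id <- oid
      df$parent_id <- pid
    }
    ## detection drops
    if (drop_rate > 0) {
      keep <- stats::runif(nrow(df)) >= drop_rate
      df <- df[keep, , drop = FALSE]
    }
    ## whole-frame drops
    if (frame_drop_rate > 0) {
      fkey <- unique(df[, c("fov", "frame")])
      dropped <- fkey[stats::runif(nrow(fkey)) < frame_drop_rate, ,
                      drop = FALSE]
      if (nrow(dropped) > 0) {
        bad <- paste(df$fov, df$frame, sep = "\r") %in%
          paste(dropped$fov, dropped$frame, sep = "\r")
        df <- df[!bad, , drop = FALSE]
      }
    }
    tracked_table(df, validate = FALSE)
  })
}
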