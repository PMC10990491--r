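#' Per-interval window bookkeeping for the Eulerian estimator
#'
#' For every pair of consecutive frames the living nuclei inside the
#' tracking window are counted and the change is decomposed into the
#' conservation relation
#' `N_window(t+1) - N_window(t) = N_new + N_in - N_out - N_death`.
#'
#' Classification rules:
#' * an object gained by the window set counts as a division (`N_new`)
#'   only if this is its first appearance anywhere in the table, its
#'   parent id is set, and the parent was inside the window at the
#'   earlier frame; every other gained object counts as an inflow
#'   (`N_in`).  First-seen unparented objects away from the window
#'   boundary are logged as anomalies (and counted in `N_in`).
#' * an object lost by the window set counts as a death (`N_death`) if it
#'   is flagged dead at the later frame, as an outflow (`N_out`) if it is
#'   alive outside the window, and as an outflow-with-anomaly if it
#'   disappeared from the table entirely (lost detection).
#'
#' Death flags are first projected to an irreversible per-object death
#' frame (the start of the terminal run of dead records), which makes the
#' death bookkeeping robust to isolated flag errors from identity swaps.
#' Only living nuclei are counted, both in the window population and in
#' the flux terms.
#'
#' @param table a single-fov [tracked_table()].
#' @param window a [tracking_window()].
#' @param interior_margin distance (px) from the window boundary beyond
#'   which an unparented first appearance is considered anomalous.
#' @return a data.frame of class `frame_counts` with one row per
#'   consecutive-frame interval: `t_start`, `t_end`, `n_start`, `n_end`,
#'   `n_new`, `n_in`, `n_out`, `n_death`, `n_anomaly`.
#' @export
frame_counts <- function(table, window = tracking_window(),
                         interior_margin = 50) {
  stopifnot(inherits(table, "tracked_table"))
  if (nrow(table) == 0) stopf("empty table")
  if (length(unique(table$fov)) > 1) {
    stopf("frame_counts expects a single field of view; split by fov first")
  }
  frames <- sort(unique(table$frame))
  if (length(frames) < 2) stopf("single-frame table: no intervals")
  frame_time <- tapply(table$time, table$frame, `[`, 1)
  times <- as.numeric(frame_time[as.character(frames)])

  ids <- table$object_id
  uid <- unique(ids)
  idx_of <- match(ids, uid)
  ## per-object first appearance and irreversible death frame
  first_frame <- rep(Inf, length(uid))
  parent_of <- rep(NA_character_, length(uid))
  ord <- order(idx_of, table$frame)
  fo <- table$frame[ord]; io <- idx_of[ord]; do <- table$dead[ord]
  po <- as.character(table$parent_id[ord])
  newobj <- c(TRUE, io[-1] != io[-length(io)])
  first_frame[io[newobj]] <- fo[newobj]
  parent_of[io[newobj]] <- po[newobj]
  ## irreversible death frame: first dead record confirmed by the object's
  ## next appearance also being dead (or being its final appearance) --
  ## robust to isolated flag errors introduced by identity swaps
  death_frame <- rep(NA_real_, length(uid))
  runs <- split(seq_along(io), io)
  for (j in seq_along(runs)) {
    rr <- runs[[j]]
    d <- do[rr]
    n <- length(d)
    confirmed <- d & c(d[-1], TRUE)
    if (any(confirmed)) {
      death_frame[io[rr[1]]] <- fo[rr[which(confirmed)[1]]]
    }
  }

  eff_dead <- !is.na(death_frame[idx_of]) & table$frame >= death_frame[idx_of]
  inside <- in_window(table$x, table$y, window)
  near_boundary <-
    (table$x < window$x_min + interior_margin) |
    (table$x >= window$x_max - interior_margin) |
    (table$y < window$y_min + interior_margin) |
    (table$y >= window$y_max - interior_margin)

  by_frame <- split(seq_len(nrow(table)), table$frame)
  nk <- length(frames) - 1
  out <- data.frame(
    t_start = times[-length(times)], t_end = times[-1],
    n_start = integer(nk), n_end = integer(nk),
    n_new = integer(nk), n_in = integer(nk), n_out = integer(nk),
    n_death = integer(nk), n_anomaly = integer(nk)
  )
  for (k in seq_len(nk)) {
    r1 <- by_frame[[as.character(frames[k])]]
    r2 <- by_frame[[as.character(frames[k + 1])]]
    w1 <- r1[!eff_dead[r1] & inside[r1]]
    w2 <- r2[!eff_dead[r2] & inside[r2]]
    W1 <- idx_of[w1]
    W2 <- idx_of[w2]
    out$n_start[k] <- length(W1)
    out$n_end[k] <- length(W2)

    gained <- w2[!(W2 %in% W1)]
    lost_ids <- W1[!(W1 %in% W2)]

    n_new <- 0L; n_in <- 0L; n_anom <- 0L
    for (r in gained) {
      o <- idx_of[r]
      is_first <- first_frame[o] == frames[k + 1]
      par <- parent_of[o]
      par_idx <- if (!is.na(par)) match(par, uid) else NA_integer_
      if (is_first && !is.na(par_idx) && par_idx %in% W1) {
        n_new <- n_new + 1L
      } else {
        n_in <- n_in + 1L
        if (is_first && is.na(par_idx) && !near_boundary[r]) {
          n_anom <- n_anom + 1L
        }
      }
    }
    n_out <- 0L; n_death <- 0L
    at2 <- idx_of[r2]
    for (o in lost_ids) {
      pos <- match(o, at2)
      if (is.na(pos)) {
        n_out <- n_out + 1L            # lost detection
        n_anom <- n_anom + 1L
      } else if (eff_dead[r2[pos]]) {
        n_death <- n_death + 1L
      } else {
        n_out <- n_out + 1L
      }
    }
    out$n_new[k] <- n_new
    out$n_in[k] <- n_in
    out$n_out[k] <- n_out
    out$n_death[k] <- n_death
    out$n_anomaly[k] <- n_anom
  }
  attr(out, "window") <- window
  attr(out, "fov") <- table$fov[1]
  class(out) <- c("frame_counts", "data.frame")
  out
}

#' Check the window conservation identity
#'
#' @param counts a [frame_counts()] result.
#' @return integer vector of per-interval violations of
#'   `n_end - n_start = n_new + n_in - n_out - n_death` (all zero on any
#'   table whose gains and losses are classified).
#' @export
check_conservation <- function(counts) {
  stopifnot(inherits(counts, "frame_counts"))
  (counts$n_end - counts$n_start) -
    (counts$n_new + counts$n_in - counts$n_out - counts$n_death)
}

#' Average per-capita rate from cumulative normalized event counts
#'
#' The Eulerian estimator: for each interval the number of events
#' (divisions or deaths) inside the tracking window is divided by the
#' living-cell count, and the slope of the ordinary least-squares
#' regression (free intercept) of the cumulative sum of these ratios
#' against interval end time is the average per-capita rate over
#' `[t0, t1]` in min^-1.
#'
#' When a periodic `schedule` is supplied, `t0` defaults to the end of
#' acclimation and intervals overlapping an incomplete final fluctuation
#' period are excluded.  Intervals with a zero living-cell denominator
#' are skipped (reported in the return value).
#'
#' @param counts a [frame_counts()] result.
#' @param event_type `"division"` or `"death"`.
#' @param t0,t1 analysis bounds in minutes (defaults: full usable range).
#' @param schedule optional [make_schedule()] schedule driving acclimation
#'   and incomplete-period exclusion.
#' @param denominator which window count normalizes each interval:
#'   `"start"` (default), `"end"`, or `"mean"` of the two.
#' @return an object of class `rate_estimate`: `rate` (min^-1),
#'   `intercept`, `stderr`, `n_intervals`, `t0`, `t1`, `event_type`,
#'   `skipped_zero_denominator`.
#' @export
mean_rate <- function(counts, event_type = c("division", "death"),
                      t0 = NULL, t1 = NULL, schedule = NULL,
                      denominator = c("start", "end", "mean")) {
  stopifnot(inherits(counts, "frame_counts"))
  event_type <- match.arg(event_type)
  denominator <- match.arg(denominator)
  if (!is.null(schedule)) stopifnot(inherits(schedule, "env_schedule"))
  t0 <- t0 %||% if (!is.null(schedule)) schedule$acclimation else
    min(counts$t_start)
  t1_max <- max(counts$t_end)
  if (is.null(t1)) {
    t1 <- t1_max
    if (!is.null(schedule) && schedule$regime %in% periodic_regimes()) {
      Tp <- schedule$period
      n_complete <- floor((t1_max - schedule$acclimation) / Tp)
      t1 <- min(t1_max, schedule$acclimation + n_complete * Tp)
    }
  }
  use <- counts[counts$t_start >= t0 & counts$t_end <= t1, , drop = FALSE]
  denom <- switch(denominator,
                  start = use$n_start,
                  end = use$n_end,
                  mean = (use$n_start + use$n_end) / 2)
  zero <- denom <= 0
  if (any(zero)) {
    warnf("%d interval(s) with zero living-cell denominator skipped",
          sum(zero))
    use <- use[!zero, , drop = FALSE]
    denom <- denom[!zero]
  }
  if (nrow(use) < 3) {
    stopf("need at least 3 usable intervals in [%g, %g] (have %d)",
          t0, t1, nrow(use))
  }
  events <- if (event_type == "division") use$n_new else use$n_death
  y <- cumsum(events / denom)
  fit <- stats::lm(y ~ use$t_end)
  ## event-free or perfectly regular series fit exactly; the perfect-fit
  ## warning from summary.lm carries no information here
  sm <- suppressWarnings(summary(fit))
  structure(
    list(rate = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         stderr = unname(sm$coefficients[2, 2]),
         r_squared = sm$r.squared,
         n_intervals = nrow(use),
         t0 = t0, t1 = t1,
         event_type = event_type,
         denominator = denominator,
         skipped_zero_denominator = sum(zero)),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s rate: %.4g min^-1 (se %.2g, %d intervals, [%g, %g] min)\n",
              x$event_type, x$rate, x$stderr, x$n_intervals, x$t0, x$t1))
  invisible(x)
}

#' Instantaneous rates from sliding windows
#'
#' Applies the cumulative-sum slope estimator inside a sliding window
#' (default 36 min wide, stepped every 6 min) centered on each output
#' time.  Windows at the edges of the series are truncated rather than
#' dropped, and flagged.
#'
#' @param counts a [frame_counts()] result.
#' @param width window width in minutes.
#' @param step step between window centers in minutes.
#' @param event_type `"division"` or `"death"`.
#' @param denominator see [mean_rate()].
#' @return a data.frame of class `rate_series`: `time` (window center),
#'   `rate` (min^-1, `NA` where fewer than 2 intervals fall in the
#'   window), `n_intervals`, `truncated`.
#' @export
instantaneous_rates <- function(counts, width = 36, step = 6,
                                event_type = c("division", "death"),
                                denominator = c("start", "end", "mean")) {
  stopifnot(inherits(counts, "frame_counts"))
  event_type <- match.arg(event_type)
  denominator <- match.arg(denominator)
  lo <- min(counts$t_start); hi <- max(counts$t_end)
  if (hi - lo < width) stopf("series (%g min) shorter than one window (%g min)",
                             hi - lo, width)
  centers <- seq(lo, hi, by = step)
  denom_all <- switch(denominator,
                      start = counts$n_start,
                      end = counts$n_end,
                      mean = (counts$n_start + counts$n_end) / 2)
  events_all <- if (event_type == "division") counts$n_new else counts$n_death
  rate <- rep(NA_real_, length(centers))
  n_int <- integer(length(centers))
  trunc_flag <- logical(length(centers))
  for (i in seq_along(centers)) {
    a <- centers[i] - width / 2
    b <- centers[i] + width / 2
    sel <- counts$t_start >= a & counts$t_end <= b & denom_all > 0
    n_int[i] <- sum(sel)
    trunc_flag[i] <- a < lo || b > hi
    if (n_int[i] >= 2) {
      y <- cumsum(events_all[sel] / denom_all[sel])
      tt <- counts$t_end[sel]
      rate[i] <- unname(stats::coef(stats::lm(y ~ tt))[2])
    }
  }
  out <- data.frame(time = centers, rate = rate, n_intervals = n_int,
                    truncated = trunc_flag)
  attr(out, "event_type") <- event_type
  attr(out, "step") <- step
  attr(out, "width") <- width
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Phase-folded rate profile over the fluctuation period
#'
#' Pools rate observations from one or more fields of view across all
#' complete fluctuation periods, assigns each observation to its phase
#' within the period, and averages per phase bin (bin width = sampling
#' step).  Also reports the mean rate over all data collected in each
#' half-period.
#'
#' Input can be a list of [frame_counts()] tables (each interval then
#' contributes one per-capita rate observation `events / N / dt` at its
#' midpoint phase — the per-6-min-window dots of the experimental
#' figures) or a list of [instantaneous_rates()] series (each non-`NA`
#' point contributes at its center's phase).
#'
#' @param series_list a list of `frame_counts` or `rate_series` objects
#'   (a bare single object is accepted).
#' @param schedule a periodic [make_schedule()] schedule.
#' @param event_type used when folding `frame_counts`.
#' @param denominator used when folding `frame_counts`.
#' @param bin_width phase bin width in minutes (default 6).
#' @return an object of class `phase_profile`: `period`, `bins` (a
#'   data.frame with `phase_center`, `mean_rate`, `ci95_low`, `ci95_high`,
#'   `n_obs`), and `half_period_means` (named vector `first`, `second`
#'   with `first_ci`/`second_ci` attributes as a list member
#'   `half_period_ci`).
#' @export
fold_by_phase <- function(series_list, schedule,
                          event_type = c("division", "death"),
                          denominator = c("start", "end", "mean"),
                          bin_width = 6) {
  stopifnot(inherits(schedule, "env_schedule"))
  if (!schedule$regime %in% periodic_regimes()) {
    stopf("phase folding requires a periodic schedule")
  }
  event_type <- match.arg(event_type)
  denominator <- match.arg(denominator)
  if (inherits(series_list, "frame_counts") ||
      inherits(series_list, "rate_series")) {
    series_list <- list(series_list)
  }
  Tp <- schedule$period
  obs_t <- numeric(0); obs_r <- numeric(0); cover_end <- -Inf
  for (s in series_list) {
    if (inherits(s, "frame_counts")) {
      denom <- switch(denominator,
                      start = s$n_start, end = s$n_end,
                      mean = (s$n_start + s$n_end) / 2)
      ev <- if (event_type == "division") s$n_new else s$n_death
      mid <- (s$t_start + s$t_end) / 2
      keep <- denom > 0 & mid >= schedule$acclimation
      r <- ev[keep] / denom[keep] / (s$t_end - s$t_start)[keep]
      obs_t <- c(obs_t, mid[keep]); obs_r <- c(obs_r, r)
      cover_end <- max(cover_end, s$t_end)
    } else if (inherits(s, "rate_series")) {
      keep <- !is.na(s$rate) & s$time >= schedule$acclimation
      obs_t <- c(obs_t, s$time[keep]); obs_r <- c(obs_r, s$rate[keep])
      cover_end <- max(cover_end, s$time)
    } else {
      stopf("series_list must contain frame_counts or rate_series objects")
    }
  }
  ## exclude observations beyond the last complete period of the data
  n_complete <- floor((cover_end - schedule$acclimation) / Tp)
  if (n_complete < 1) stopf("no complete fluctuation period in the data")
  cutoff <- schedule$acclimation + n_complete * Tp
  keep <- obs_t < cutoff
  obs_t <- obs_t[keep]; obs_r <- obs_r[keep]
  if (length(obs_t) == 0) stopf("no usable observations after exclusions")

  ph <- phase_of(schedule, obs_t)
  bin <- floor(ph$phase / bin_width)
  centers <- (sort(unique(bin)) + 0.5) * bin_width
  stats_by <- lapply(sort(unique(bin)), function(b) t_ci(obs_r[bin == b]))
  bins <- data.frame(
    phase_center = centers,
    mean_rate = vapply(stats_by, `[[`, numeric(1), "mean"),
    ci95_low = vapply(stats_by, `[[`, numeric(1), "ci_low"),
    ci95_high = vapply(stats_by, `[[`, numeric(1), "ci_high"),
    n_obs = vapply(stats_by, `[[`, numeric(1), "n")
  )
  first <- ph$half == "first"
  hm <- c(first = mean(obs_r[first]), second = mean(obs_r[!first]))
  structure(
    list(period = Tp, bins = bins, half_period_means = hm,
         half_period_ci = list(first = t_ci(obs_r[first]),
                               second = t_ci(obs_r[!first])),
         n_obs_total = length(obs_r), event_type = event_type),
    class = "phase_profile"
  )
}

#' @export
print.phase_profile <- function(x, ...) {
  cat(sprintf("<phase_profile> period %g min, %d bins, %d observations\n",
              x$period, nrow(x$bins), x$n_obs_total))
  cat(sprintf("  half-period mean %s rates: first %.4g, second %.4g min^-1\n",
              x$event_type, x$half_period_means["first"],
              x$half_period_means["second"]))
  invisible(x)
}

#' Population growth rate
#'
#' The fitness proxy: per-capita division rate minus per-capita death
#' rate.  Accepts plain numbers or [mean_rate()] estimates (whose
#' analysis intervals are compared, with a warning on mismatch).
#'
#' @param division,death rates in min^-1, as numbers or `rate_estimate`s.
#' @return growth rate in min^-1 (numeric).
#' @export
population_growth_rate <- function(division, death) {
  get_rate <- function(z) if (inherits(z, "rate_estimate")) z$rate else z
  if (inherits(division, "rate_estimate") && inherits(death, "rate_estimate")) {
    if (!isTRUE(all.equal(c(division$t0, division$t1),
                          c(death$t0, death$t1)))) {
      warnf("division and death estimates cover different intervals")
    }
  }
  get_rate(division) - get_rate(death)
}

#' Doubling time from a per-capita division rate
#'
#' `ln(2) / rate`, in minutes.  Conventionally reported rounded to the
#' nearest minute; the full-precision value is returned.
#'
#' @param rate division rate in min^-1 (> 0).
#' @return doubling time in minutes.
#' @export
doubling_time <- function(rate) {
  if (any(!is.finite(rate) | rate <= 0)) {
    stopf("doubling time undefined for non-positive rate")
  }
  log(2) / rate
}

#' Fluctuation period from a frequency
#'
#' @param freq frequency in min^-1 (> 0).
#' @return period in minutes (full precision; report rounded to the
#'   nearest minute).
#' @export
period_from_frequency <- function(freq) {
  if (any(!is.finite(freq) | freq <= 0)) {
    stopf("period undefined for non-positive frequency")
  }
  1 / freq
}

#' Replicate summary: mean with 95% confidence interval
#'
#' Summarizes per-chamber (per field of view) rates as a mean with a
#' t-distribution 95% confidence interval (n - 1 degrees of freedom).
#' With a single replicate the mean is returned and the interval is
#' undefined (`NA`).
#'
#' @param values numeric vector of per-chamber rates.
#' @return list with `mean`, `ci_low`, `ci_high`, `n`, `sd`.
#' @export
replicate_summary <- function(values) {
  if (length(values) == 0) stopf("no values supplied")
  t_ci(values)
}

#' Compare two conditions with a t-test
#'
#' Two-sample t-test on per-chamber mean rates; Welch's unequal-variance
#' form by default (chamber variances need not match), classic Student's
#' test via `var_equal = TRUE`.
#'
#' @param group_a,group_b numeric vectors of per-chamber rates (each of
#'   length >= 2).
#' @param var_equal assume equal variances (Student) instead of Welch.
#' @return list with `t`, `p_value`, `df`, `mean_a`, `mean_b`, `method`.
#' @export
compare_conditions <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stopf("each group needs at least 2 replicates")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b),
       method = ht$method)
}
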