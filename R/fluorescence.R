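#' Construct a per-cell fluorescence trace table
#'
#' @param df data.frame with columns `fov`, `object_id`, `frame`, `time`,
#'   `cell_mean_fluor`, `cell_area`, and optionally `nucleus_mean_fluor`,
#'   `nucleus_area`.
#' @return the validated table with class `cell_traces`.
#' @export
cell_traces <- function(df) {
  required <- c("fov", "object_id", "frame", "time", "cell_mean_fluor",
                "cell_area")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(df$cell_mean_fluor < 0, na.rm = TRUE)) {
    stopf("negative fluorescence values")
  }
  if (!is.null(df$nucleus_area) &&
      any(df$nucleus_area > df$cell_area, na.rm = TRUE)) {
    stopf("nucleus_area exceeds cell_area")
  }
  class(df) <- unique(c("cell_traces", class(df)))
  df
}

filter_track_length <- function(traces, min_track_minutes) {
  if (min_track_minutes <= 0) return(traces)
  span <- tapply(traces$time, paste(traces$fov, traces$object_id, sep = "\r"),
                 function(t) max(t) - min(t))
  keep_ids <- names(span)[span >= min_track_minutes]
  out <- traces[paste(traces$fov, traces$object_id, sep = "\r") %in% keep_ids,
                , drop = FALSE]
  class(out) <- class(traces)
  out
}

#' Across-cell population curve
#'
#' At each time point, the mean of a per-cell quantity across the cells
#' present at that time, with a t-based 95% confidence interval.  Cells
#' absent at a time point are omitted (no imputation).
#'
#' @param per_cell data.frame with columns `object_id`, `time` and the
#'   value column.
#' @param value_col name of the value column.
#' @param times optional time points to report (default: all observed).
#' @return data.frame with `time`, `mean`, `ci95_low`, `ci95_high`, `n`.
#' @export
population_curve <- function(per_cell, value_col, times = NULL) {
  if (!value_col %in% names(per_cell)) {
    stopf("no column '%s' in per-cell data", value_col)
  }
  times <- times %||% sort(unique(per_cell$time))
  rows <- lapply(times, function(tt) {
    v <- per_cell[[value_col]][per_cell$time == tt]
    if (length(v) == 0) stopf("no cells observed at time %g", tt)
    s <- t_ci(v)
    data.frame(time = tt, mean = s$mean, ci95_low = s$ci_low,
               ci95_high = s$ci_high, n = s$n)
  })
  do.call(rbind, rows)
}

#' Reporter fold change relative to the baseline population
#'
#' For each cell and frame,
#' `FC_i(t) = (F_i(t) - Fbar(t0)) / Fbar(t0)`
#' where `Fbar(t0)` is the mean fluorescence across all cells at the
#' baseline frame.  The baseline defaults to the first frame of the
#' table; analyses that exclude an acclimation phase should pass the
#' first post-acclimation frame.
#'
#' @param traces a [cell_traces()] table.
#' @param baseline_frame frame index of the baseline (default: first).
#' @param min_track_minutes drop cells tracked for a shorter span
#'   (default 0; the curation used for reporter figures corresponds to
#'   360 min).
#' @return list with `per_cell` (columns `fov`, `object_id`, `time`,
#'   `fold_change`), `population` (a [population_curve()]),
#'   `baseline_mean` and `baseline_frame`.
#' @export
fold_change <- function(traces, baseline_frame = NULL,
                        min_track_minutes = 0) {
  stopifnot(inherits(traces, "cell_traces"))
  traces <- filter_track_length(traces, min_track_minutes)
  baseline_frame <- baseline_frame %||% min(traces$frame)
  base <- traces$cell_mean_fluor[traces$frame == baseline_frame]
  if (length(base) == 0) stopf("no cells at baseline frame %s",
                               baseline_frame)
  f0 <- mean(base)
  if (!is.finite(f0) || f0 <= 0) {
    stopf("baseline population mean must be positive (got %g)", f0)
  }
  per_cell <- data.frame(
    fov = traces$fov, object_id = traces$object_id,
    time = traces$time, frame = traces$frame,
    fold_change = (traces$cell_mean_fluor - f0) / f0,
    stringsAsFactors = FALSE
  )
  list(per_cell = per_cell,
       population = population_curve(per_cell, "fold_change"),
       baseline_mean = f0,
       baseline_frame = baseline_frame)
}

#' Nuclear enrichment of fluorescence
#'
#' Per cell and frame, the mean fluorescence of the nucleus divided by
#' the mean fluorescence of the whole cell (whose pixels include the
#' nucleus).  Values above 1 indicate nuclear accumulation of the tagged
#' protein.  The raw ratio is returned; an optional pre-stimulus baseline
#' division is exposed for normalized displays.
#'
#' @param traces a [cell_traces()] table with nuclear columns.
#' @param baseline_normalize divide each cell's series by its own mean
#'   enrichment over `baseline_times` (default off).
#' @param baseline_times times (minutes) defining the per-cell baseline
#'   when `baseline_normalize = TRUE`.
#' @param min_track_minutes drop cells tracked for a shorter span.
#' @return list with `per_cell` (columns `fov`, `object_id`, `time`,
#'   `enrichment`) and `population` (a [population_curve()]).
#' @export
nuclear_enrichment <- function(traces, baseline_normalize = FALSE,
                               baseline_times = NULL,
                               min_track_minutes = 0) {
  stopifnot(inherits(traces, "cell_traces"))
  if (is.null(traces$nucleus_mean_fluor)) {
    stopf("missing nucleus_mean_fluor column")
  }
  traces <- filter_track_length(traces, min_track_minutes)
  if (any(traces$cell_mean_fluor <= 0)) {
    stopf("zero cell mean fluorescence: enrichment undefined")
  }
  enr <- traces$nucleus_mean_fluor / traces$cell_mean_fluor
  per_cell <- data.frame(
    fov = traces$fov, object_id = traces$object_id,
    time = traces$time, frame = traces$frame,
    enrichment = enr, stringsAsFactors = FALSE
  )
  if (baseline_normalize) {
    if (is.null(baseline_times)) {
      stopf("baseline_normalize requires baseline_times")
    }
    key <- paste(per_cell$fov, per_cell$object_id, sep = "\r")
    basal <- tapply(per_cell$enrichment[per_cell$time %in% baseline_times],
                    key[per_cell$time %in% baseline_times], mean)
    per_cell$enrichment <- per_cell$enrichment / as.numeric(basal[key])
  }
  list(per_cell = per_cell,
       population = population_curve(per_cell, "enrichment"))
}

#' Relative fluorescence of a fluorescein calibration series
#'
#' `RF_t = (F_t - F_min) / (F_max - F_min)`, where `F_min` and `F_max`
#' are the mean fluorescence over configured calibration windows (the
#' standard assay dispenses fluorescein for 20 min twice: maxima over
#' 10-20 and 50-60 min, minima over 30-40 and 70-80 min).  Values are not
#' clipped to `[0, 1]`; out-of-range points are flagged to preserve
#' diagnostic information about calibration drift.
#'
#' @param series data.frame with columns `time`, `fluor` and optionally
#'   `region`; with a region column the normalization is computed per
#'   region.
#' @param min_windows,max_windows lists of `c(start, end)` intervals in
#'   minutes (inclusive bounds) over which `F_min`/`F_max` are averaged.
#' @return the series with added columns `rf` and `out_of_range`, plus
#'   attributes `f_min` and `f_max` (named by region).
#' @export
relative_fluorescence <- function(series,
                                  min_windows = list(c(30, 40), c(70, 80)),
                                  max_windows = list(c(10, 20), c(50, 60))) {
  if (!all(c("time", "fluor") %in% names(series))) {
    stopf("series requires columns 'time' and 'fluor'")
  }
  region <- if ("region" %in% names(series)) series$region else "all"
  in_windows <- function(t, windows) {
    Reduce(`|`, lapply(windows, function(w) t >= w[1] & t <= w[2]))
  }
  sel_min <- in_windows(series$time, min_windows)
  sel_max <- in_windows(series$time, max_windows)
  if (!any(sel_min) || !any(sel_max)) {
    stopf("calibration windows not covered by the series")
  }
  out <- series
  out$rf <- NA_real_
  fmins <- c(); fmaxs <- c()
  for (rg in unique(region)) {
    rows <- region == rg
    f_min <- mean(series$fluor[rows & sel_min])
    f_max <- mean(series$fluor[rows & sel_max])
    if (!(f_max > f_min)) {
      stopf("region %s: F_max (%g) must exceed F_min (%g)", rg, f_max, f_min)
    }
    out$rf[rows] <- (series$fluor[rows] - f_min) / (f_max - f_min)
    fmins[rg] <- f_min; fmaxs[rg] <- f_max
  }
  out$out_of_range <- out$rf < 0 | out$rf > 1
  attr(out, "f_min") <- fmins
  attr(out, "f_max") <- fmaxs
  out
}
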