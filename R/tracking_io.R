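#' Tracking window
#'
#' The fixed spatial region within which all Eulerian counts are taken.
#' The default follows the analysis convention of a 1928 x 1928 pixel
#' window centered in a 2048 x 2048 field of view (60 px margins).
#' Window membership uses the nucleus centroid with half-open bounds
#' `[min, max)`.
#'
#' @param frame_size side of the (square) field of view in pixels.
#' @param window_size side of the (square) centered window in pixels.
#' @param x_min,x_max,y_min,y_max explicit bounds; when supplied they
#'   override the centered construction.
#' @return an object of class `tracking_window`.
#' @export
tracking_window <- function(frame_size = 2048, window_size = 1928,
                            x_min = NULL, x_max = NULL,
                            y_min = NULL, y_max = NULL) {
  if (is.null(x_min)) {
    if (window_size > frame_size) stopf("window larger than frame")
    margin <- (frame_size - window_size) / 2
    x_min <- margin; x_max <- frame_size - margin
    y_min <- margin; y_max <- frame_size - margin
  }
  if (x_max <= x_min || y_max <= y_min) stopf("degenerate tracking window")
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "tracking_window")
}

#' @export
print.tracking_window <- function(x, ...) {
  cat(sprintf("<tracking_window> x [%g, %g) | y [%g, %g)\n",
              x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

in_window <- function(x, y, window) {
  x >= window$x_min & x < window$x_max & y >= window$y_min & y < window$y_max
}

tracking_columns <- function() {
  c("fov", "frame", "time", "object_id", "parent_id", "x", "y", "size",
    "dead")
}

#' Construct and validate a tracked-nuclei table
#'
#' One row per detected nucleus per frame.  Required columns: `fov`,
#' `frame` (integer index), `time` (minutes), `object_id`, `parent_id`
#' (`NA` for unparented objects), `x`, `y` (pixel centroid), `size`
#' (nucleus area, pixels).  A logical `dead` column is optional and
#' defaults to `FALSE`.
#'
#' Structural errors (missing columns, duplicated `(fov, frame,
#' object_id)`, time not strictly increasing with frame within a fov) are
#' fatal.  Lineage and death-monotonicity violations are reported as
#' warnings only, because tables corrupted by tracking errors must still
#' be representable.
#'
#' @param df a data.frame of records.
#' @param validate logical; skip all checks when `FALSE`.
#' @return the table, sorted by `(fov, frame, object_id)`, with class
#'   `tracked_table`.
#' @export
tracked_table <- function(df, validate = TRUE) {
  required <- setdiff(tracking_columns(), "dead")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  if (is.null(df$dead)) df$dead <- logical(nrow(df))
  df$dead <- as.logical(df$dead)
  df <- df[, tracking_columns(), drop = FALSE]
  df <- df[order(df$fov, df$frame, df$object_id), , drop = FALSE]
  rownames(df) <- NULL
  if (validate && nrow(df) > 0) {
    key <- paste(df$fov, df$frame, df$object_id, sep = "\r")
    if (anyDuplicated(key) > 0) {
      stopf("duplicate (fov, frame, object_id) record(s), e.g. %s",
            gsub("\r", "/", key[anyDuplicated(key)]))
    }
    for (fv in unique(df$fov)) {
      sub <- df[df$fov == fv, c("frame", "time")]
      sub <- unique(sub[order(sub$frame), ])
      if (anyDuplicated(sub$frame) > 0) {
        stopf("fov %s: a frame maps to more than one time", fv)
      }
      if (any(diff(sub$time) <= 0)) {
        stopf("fov %s: time is not strictly increasing with frame", fv)
      }
    }
    viol <- death_monotonicity_violations(df)
    if (viol > 0) {
      warnf("%d record(s) violate death monotonicity (dead then alive)", viol)
    }
  }
  class(df) <- c("tracked_table", "data.frame")
  df
}

death_monotonicity_violations <- function(df) {
  if (!any(df$dead)) return(0L)
  ord <- order(df$fov, df$object_id, df$frame)
  d <- df$dead[ord]
  id <- paste(df$fov, df$object_id, sep = "\r")[ord]
  same <- c(FALSE, id[-1] == id[-length(id)])
  sum(same & !d & c(FALSE, d[-length(d)]))
}

#' Read a per-field-of-view object-tracking table from CSV
#'
#' The expected dialect is comma-separated UTF-8 with a header row and an
#' empty string for a null `parent_id`.  Foreign exporters can be
#' accommodated with `column_map`, a named character vector mapping
#' canonical names to the file's column names, e.g.
#' `c(object_id = "labelimageId")`.
#'
#' @param path CSV file path.
#' @param column_map optional named character vector of column renames.
#' @param quiet suppress the per-fov row-count message.
#' @return a [tracked_table()].
#' @export
read_tracking_table <- function(path, column_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      foreign <- column_map[[canonical]]
      if (!foreign %in% names(raw)) {
        stopf("column_map names absent column '%s'", foreign)
      }
      names(raw)[names(raw) == foreign] <- canonical
    }
  }
  required <- setdiff(tracking_columns(), "dead")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  ## ids are kept as written, except purely numeric labels which become
  ## integers so ordering matches the exporter's
  as_id <- function(v) {
    v[!is.na(v) & v == ""] <- NA_character_
    if (all(grepl("^[0-9]+$", v[!is.na(v)])) && any(!is.na(v))) {
      as.integer(v)
    } else {
      v
    }
  }
  df <- data.frame(
    fov = raw$fov,
    frame = as.integer(raw$frame),
    time = as.numeric(raw$time),
    object_id = as_id(raw$object_id),
    parent_id = as_id(raw$parent_id),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y),
    size = as.numeric(raw$size),
    stringsAsFactors = FALSE
  )
  df$dead <- if ("dead" %in% names(raw)) {
    as.logical(toupper(raw$dead) %in% c("TRUE", "T", "1"))
  } else {
    logical(nrow(df))
  }
  tab <- tracked_table(df)
  if (!quiet) {
    counts <- table(tab$fov)
    message("read ", nrow(tab), " records: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  tab
}

#' Write a tracked table to CSV
#'
#' Fixed header order, full float precision, null `parent_id` written as
#' an empty string, so that `read_tracking_table()` reproduces the table
#' exactly.
#'
#' @param table a [tracked_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(table, path) {
  stopifnot(inherits(table, "tracked_table"))
  out <- as.data.frame(table)
  for (col in c("time", "x", "y", "size")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  out$parent_id <- ifelse(is.na(out$parent_id), "", as.character(out$parent_id))
  out$dead <- ifelse(out$dead, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Annotate observed cell deaths
#'
#' Mirrors the manual curation step in which a death flag is added to the
#' tracking CSV: each event `(fov, object_id, frame)` marks the object as
#' dead from that frame onward.  Multiple events for one object resolve to
#' the earliest frame (death is irreversible), making the operation
#' idempotent.
#'
#' @param table a [tracked_table()].
#' @param death_events data.frame with columns `fov`, `object_id`, `frame`.
#' @return the annotated table.
#' @export
annotate_deaths <- function(table, death_events) {
  stopifnot(inherits(table, "tracked_table"))
  if (is.null(death_events) || nrow(death_events) == 0) return(table)
  need <- c("fov", "object_id", "frame")
  if (!all(need %in% names(death_events))) {
    stopf("death_events requires columns: %s", paste(need, collapse = ", "))
  }
  key_tab <- paste(table$fov, table$object_id, sep = "\r")
  for (i in seq_len(nrow(death_events))) {
    ev <- death_events[i, ]
    key <- paste(ev$fov, ev$object_id, sep = "\r")
    rows <- which(key_tab == key)
    if (length(rows) == 0) {
      stopf("death event %d: unknown object %s in fov %s",
            i, ev$object_id, ev$fov)
    }
    if (ev$frame < min(table$frame[rows])) {
      stopf("death event %d: frame %d precedes first appearance (frame %d)",
            i, ev$frame, min(table$frame[rows]))
    }
    if (!any(table$frame[rows] == ev$frame)) {
      stopf("death event %d: object %s not present at frame %d",
            i, ev$object_id, ev$frame)
    }
    hit <- rows[table$frame[rows] >= ev$frame]
    table$dead[hit] <- TRUE
  }
  table
}

#' Remove excluded frames from a tracked table
#'
#' Used to drop out-of-focus images.  Timestamps of the surviving frames
#' are untouched: downstream regressions use real time, so exclusions
#' simply create gaps in the sampling grid.
#'
#' @param table a [tracked_table()].
#' @param frames_to_exclude integer frame indices to drop.
#' @param fov optional single fov; when `NULL` the frames are dropped in
#'   every fov.
#' @param quiet suppress the message about frames that were not present.
#' @return the filtered table.
#' @export
drop_frames <- function(table, frames_to_exclude, fov = NULL, quiet = FALSE) {
  stopifnot(inherits(table, "tracked_table"))
  if (length(frames_to_exclude) == 0) return(table)
  sel <- table$frame %in% frames_to_exclude
  if (!is.null(fov)) sel <- sel & table$fov == fov
  present <- unique(table$frame[if (is.null(fov)) TRUE else table$fov == fov])
  absent <- setdiff(frames_to_exclude, present)
  if (length(absent) > 0 && !quiet) {
    message("drop_frames: ", length(absent),
            " requested frame(s) not present; ignored")
  }
  out <- table[!sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tracked_table", "data.frame")
  out
}
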