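## Fixation-log parsing and observer quality control.

#' Declare the column layout of a fixation log
#'
#' Eye-tracker exports differ in column naming and time units. A dialect maps
#' the columns of a delimited fixation log onto the fields the parser needs:
#' a timestamp, left/right eye coordinates, left/right event labels, and the
#' observer/image grouping columns.
#'
#' @param time,lx,ly,rx,ry,l_event,r_event Column names in the file.
#' @param observer,image Grouping columns (one trial per observer-image pair).
#' @param time_unit One of `"us"`, `"ms"`, `"s"`; timestamps are converted to
#'   seconds and rebased to zero at the first row of each trial.
#' @param sep Field delimiter.
#' @param fixation_label Event value that marks a fixation sample.
#' @param sample_period Seconds assigned as the duration of a fixation that is
#'   supported by a single sample row (a 250 Hz tracker emits one row every
#'   0.004 s).
#' @return A list of class `fixation_dialect`.
#' @export
fixation_dialect <- function(time = "time", lx = "l_x", ly = "l_y",
                             rx = "r_x", ry = "r_y",
                             l_event = "l_event", r_event = "r_event",
                             observer = "observer", image = "image",
                             time_unit = c("us", "ms", "s"), sep = "\t",
                             fixation_label = "Fixation",
                             sample_period = 0.004) {
  time_unit <- match.arg(time_unit)
  structure(list(time = time, lx = lx, ly = ly, rx = rx, ry = ry,
                 l_event = l_event, r_event = r_event,
                 observer = observer, image = image,
                 time_unit = time_unit, sep = sep,
                 fixation_label = fixation_label,
                 sample_period = sample_period),
            class = "fixation_dialect")
}

#' Construct a scanpath trial
#'
#' A trial is one observer's ordered fixation sequence over one image.
#'
#' @param observer,image Identifiers.
#' @param fixations Data frame with columns `x`, `y`, `t_on`, `dur` (pixels and
#'   seconds). Onsets must be non-decreasing and durations positive.
#' @param image_w,image_h Stimulus size in pixels.
#' @export
scanpath_trial <- function(observer, image, fixations, image_w, image_h) {
  stopifnot(is.data.frame(fixations),
            all(c("x", "y", "t_on", "dur") %in% names(fixations)))
  if (nrow(fixations)) {
    if (any(!is.finite(fixations$x)) || any(!is.finite(fixations$y)))
      stop_fmt("non-finite fixation coordinates for observer %s", observer)
    if (any(fixations$dur <= 0)) stop_fmt("fixation durations must be positive")
    if (any(fixations$t_on < 0)) stop_fmt("fixation onsets must be >= 0")
    if (is.unsorted(fixations$t_on)) stop_fmt("fixation onsets must be non-decreasing")
  }
  structure(list(observer = as.character(observer), image = as.character(image),
                 fixations = as.data.frame(fixations, stringsAsFactors = FALSE),
                 image_w = image_w, image_h = image_h),
            class = "scanpath_trial")
}

#' @export
print.scanpath_trial <- function(x, ...) {
  cat(sprintf("<scanpath_trial> observer %s, image %s: %d fixations over %.2f s (%dx%d px)\n",
              x$observer, x$image, nrow(x$fixations),
              if (nrow(x$fixations)) max(x$fixations$t_on + x$fixations$dur) else 0,
              x$image_w, x$image_h))
  invisible(x)
}

#' Parse an eye-tracker fixation log into scanpath trials
#'
#' Reads a delimited raw-sample export (one row per tracker sample, with left
#' and right eye positions and event labels), keeps rows whose event is
#' `Fixation`, and collapses consecutive same-position fixation samples into
#' single fixations whose duration is the spanned time. Timestamps are rebased
#' to zero at the start of each observer-image trial and converted to seconds.
#' When both eyes report a fixation the position is the average of the two;
#' otherwise the valid eye is used.
#'
#' @param file Path or connection to the delimited log.
#' @param dialect A [fixation_dialect()].
#' @param image_w,image_h Stimulus size in pixels, attached to every trial.
#' @return List of [scanpath_trial()] objects, in file order of first appearance.
#' @export
read_fixation_log <- function(file, dialect = fixation_dialect(),
                              image_w = 1680, image_h = 1050) {
  raw <- utils::read.delim(file, sep = dialect$sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L) return(list())
  need <- c(dialect$time, dialect$lx, dialect$ly, dialect$rx, dialect$ry,
            dialect$l_event, dialect$r_event, dialect$observer, dialect$image)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_fmt("fixation log is missing required column(s): %s",
                             paste(miss, collapse = ", "))
  unit <- switch(dialect$time_unit, us = 1e-6, ms = 1e-3, s = 1)
  key <- paste(raw[[dialect$observer]], raw[[dialect$image]], sep = "\r")
  trials <- list()
  for (k in unique(key)) {
    rows <- raw[key == k, , drop = FALSE]
    idx <- which(key == k)
    ts <- as.numeric(rows[[dialect$time]])
    if (is.unsorted(ts, strictly = FALSE))
      stop_fmt("non-monotone timestamps in fixation log at row %d",
               idx[which(diff(ts) < 0)[1] + 1L])
    t_s <- (ts - ts[1]) * unit
    l_fix <- rows[[dialect$l_event]] == dialect$fixation_label
    r_fix <- rows[[dialect$r_event]] == dialect$fixation_label
    x <- ifelse(l_fix & r_fix, (rows[[dialect$lx]] + rows[[dialect$rx]]) / 2,
                ifelse(l_fix, rows[[dialect$lx]], rows[[dialect$rx]]))
    y <- ifelse(l_fix & r_fix, (rows[[dialect$ly]] + rows[[dialect$ry]]) / 2,
                ifelse(l_fix, rows[[dialect$ly]], rows[[dialect$ry]]))
    keep <- l_fix | r_fix
    fx <- data.frame(x = x[keep], y = y[keep], t = t_s[keep])
    fixes <- collapse_fixation_samples(fx, dialect$sample_period)
    trials[[length(trials) + 1L]] <- scanpath_trial(
      rows[[dialect$observer]][1], rows[[dialect$image]][1],
      fixes, image_w, image_h)
  }
  trials
}

## Consecutive fixation samples within 1 px of each other belong to one
## fixation; its duration is the time span of the run.
collapse_fixation_samples <- function(fx, sample_period) {
  if (nrow(fx) == 0L)
    return(data.frame(x = numeric(), y = numeric(),
                      t_on = numeric(), dur = numeric()))
  new_run <- c(TRUE, abs(diff(fx$x)) > 1 | abs(diff(fx$y)) > 1)
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(fx, run), function(g) {
    span <- max(g$t) - min(g$t)
    data.frame(x = mean(g$x), y = mean(g$y), t_on = min(g$t),
               dur = if (span > 0) span else sample_period)
  }))
  rownames(out) <- NULL
  out
}

#' Quality-filter observers by calibration accuracy
#'
#' Keeps observers whose mean horizontal and vertical calibration errors are
#' both within `k_sd` sample standard deviations of the respective means over
#' all observers. With zero spread in a direction, a zero deviation counts as
#' within bounds, so identical records all pass.
#'
#' @param records Data frame with columns `observer`, `err_x`, `err_y`
#'   (mean calibration error in degrees, per direction).
#' @param k_sd Multiplier on the standard deviation (default 2).
#' @return Character vector of retained observer ids.
#' @export
qc_filter_observers <- function(records, k_sd = 2) {
  stopifnot(is.data.frame(records),
            all(c("observer", "err_x", "err_y") %in% names(records)))
  if (nrow(records) < 2L)
    stop_fmt("at least two calibration records are needed (SD undefined)")
  if (any(records$err_x < 0 | records$err_y < 0))
    stop_fmt("calibration errors must be >= 0")
  ok_dir <- function(e) abs(e - mean(e)) <= k_sd * stats::sd(e)
  as.character(records$observer[ok_dir(records$err_x) & ok_dir(records$err_y)])
}
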