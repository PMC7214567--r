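# Measurement container: ordered timed frames of raw counts per detector
# and energy window, plus the source table needed for decay arithmetic.

normalize_source_key <- function(x) {
  vapply(strsplit(as.character(x), "+", fixed = TRUE),
         function(ids) paste(sort(ids[nzchar(ids)]), collapse = "+"), "")
}

split_source_ids <- function(key) {
  ids <- strsplit(key, "+", fixed = TRUE)[[1]]
  ids[nzchar(ids)]
}

sources_to_frame <- function(sources) {
  if (is.data.frame(sources)) {
    need <- c("source_id", "reference_activity", "reference_time",
              "half_life")
    if (!all(need %in% names(sources)))
      stop("source table must have columns: ", paste(need, collapse = ", "))
    return(sources[need])
  }
  if (inherits(sources, "radioactive_source")) sources <- list(sources)
  do.call(rbind, lapply(sources, function(s) {
    stopifnot(inherits(s, "radioactive_source"))
    data.frame(source_id = s$source_id,
               reference_activity = s$reference_activity,
               reference_time = s$reference_time,
               half_life = s$half_life)
  }))
}

#' Measurement series
#'
#' An ordered collection of timed count measurements (frames) together
#' with the radioactive sources they reference.  Each frame records a
#' detector, an energy-window name, a start time and duration on the
#' experiment clock (seconds, t = 0 at the first frame by convention),
#' raw counts, and the set of sources present; an empty source set marks a
#' background frame.
#'
#' @param measurements data frame with columns `detector_id`, `window`,
#'   `t_start` (s), `duration` (s), `counts` (>= 0) and `source_ids`
#'   (labels joined with `"+"`; `""` for background frames).
#' @param sources a data frame with columns `source_id`,
#'   `reference_activity` (Bq), `reference_time` (s), `half_life` (s), or
#'   a list of [radioactive_source()] objects.
#' @param metadata free-form provenance list (geometry label, seed, ...).
#' @return An object of class `measurement_series`.
#' @export
measurement_series <- function(measurements, sources, metadata = list()) {
  need <- c("detector_id", "window", "t_start", "duration", "counts",
            "source_ids")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements)))
    stop("'measurements' must have columns: ", paste(need, collapse = ", "))
  m <- measurements[need]
  if (any(!(m$duration > 0))) stop("all durations must be > 0")
  if (any(m$counts < 0)) stop("counts must be >= 0")
  m$counts <- as.numeric(m$counts)  # storage-mode-stable across I/O
  m$source_ids <- normalize_source_key(m$source_ids)
  m <- m[order(m$t_start), , drop = FALSE]
  rownames(m) <- NULL
  src <- sources_to_frame(sources)
  referenced <- unique(unlist(lapply(m$source_ids, split_source_ids)))
  missing <- setdiff(referenced, src$source_id)
  if (length(missing))
    stop("source_ids reference unknown sources: ",
         paste(missing, collapse = ", "))
  structure(list(measurements = m, sources = src, metadata = metadata),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  m <- x$measurements
  nbg <- sum(m$source_ids == "")
  cat(sprintf(paste0("<measurement series: %d frames (%d background), ",
                     "%d detector(s), %d window(s), %d source(s)>\n"),
              nrow(m), nbg, length(unique(m$detector_id)),
              length(unique(m$window)), nrow(x$sources)))
  if (!is.null(x$metadata$geometry))
    cat("  geometry:", x$metadata$geometry, "\n")
  invisible(x)
}

#' @export
summary.measurement_series <- function(object, ...) {
  m <- object$measurements
  src <- m[m$source_ids != "", , drop = FALSE]
  out <- list(
    n_frames = nrow(m),
    n_background = sum(m$source_ids == ""),
    detectors = unique(m$detector_id),
    windows = unique(m$window),
    time_span_s = if (nrow(m)) diff(range(m$t_start)) else 0,
    rate_range_cps = if (nrow(src)) range(src$counts / src$duration)
                     else c(NA, NA))
  class(out) <- "summary.measurement_series"
  out
}

#' @export
print.summary.measurement_series <- function(x, ...) {
  cat(sprintf("Frames: %d (%d background)\n", x$n_frames, x$n_background))
  cat("Detectors:", paste(x$detectors, collapse = ", "), "\n")
  cat("Windows:  ", paste(x$windows, collapse = ", "), "\n")
  cat(sprintf("Time span: %.3g h; source-frame rates %.4g-%.4g kcps\n",
              x$time_span_s / 3600, x$rate_range_cps[1] / 1e3,
              x$rate_range_cps[2] / 1e3))
  invisible(x)
}

#' Background-subtracted count rate of a measurement
#'
#' Raw rate (counts / duration) minus the ambient background rate, by
#' simple subtraction.  Rates that would fall below zero are floored at 0
#' and flagged through the `"low_count"` attribute.
#'
#' @param measurement a list or data-frame row (or several rows) with
#'   fields `counts` and `duration`.
#' @param background_rate ambient rate in cps (>= 0).
#' @return Net rate(s) in cps with logical attribute `low_count`.
#' @export
net_rate <- function(measurement, background_rate = 0) {
  if (any(background_rate < 0)) stop("'background_rate' must be >= 0")
  net <- measurement$counts / measurement$duration - background_rate
  structure(pmax(net, 0), low_count = net < 0)
}

#' Pooled background rate for a detector and window
#'
#' Total counts over total duration of all background frames (frames with
#' an empty source set) for the given detector/window; pooling the frames
#' that bracket a session maximizes the counts behind the estimate.
#'
#' @param series a [measurement_series()].
#' @param detector,window labels selecting the frames.
#' @return Background rate in cps.
#' @export
background_rate <- function(series, detector, window) {
  stopifnot(inherits(series, "measurement_series"))
  m <- series$measurements
  bg <- m[m$detector_id == detector & m$window == window &
            m$source_ids == "", , drop = FALSE]
  if (!nrow(bg))
    stop("no background frames for detector '", detector,
         "', window '", window, "'")
  sum(bg$counts) / sum(bg$duration)
}

# Sum of frame-average activities of the sources present in a frame (Bq).
frame_activity <- function(series, frame) {
  ids <- split_source_ids(frame$source_ids)
  if (!length(ids)) return(0)
  src <- series$sources
  sum(vapply(ids, function(id) {
    s <- src[src$source_id == id, ]
    frame_average_activity(as.list(s), frame$t_start, frame$duration)
  }, 0))
}
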