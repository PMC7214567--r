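# Delimited-text series format: a YAML front-matter block (comment-
# prefixed) declaring format, units, metadata and the source table,
# followed by a plain CSV body.  Numbers are written with 17 significant
# digits so a write/read round trip is bit-exact.

SERIES_COLUMNS <- c("detector_id", "window", "t_start", "duration",
                    "counts", "source_ids")

fmt_num <- function(x) sprintf("%.17g", x)

unit_scale <- function(units) {
  tr <- function(u, table, what) {
    if (is.null(u)) return(1)
    if (!u %in% names(table)) stop("unknown ", what, " unit: ", u)
    table[[u]]
  }
  list(time = tr(units$time, c(s = 1, h = 3600), "time"),
       activity = tr(units$activity, c(Bq = 1, MBq = 1e6), "activity"))
}

#' Write a measurement series to a delimited text file
#'
#' The file starts with a `# ---` ... `# ---` YAML front-matter block
#' declaring the format, the units of the body columns (`time`: s or h;
#' `activity`: Bq or MBq), free-form metadata and the source table, and
#' continues as comma-separated values with the fixed column order
#' `detector_id, window, t_start, duration, counts, source_ids`
#' (source labels joined with `+`, empty for background frames).
#'
#' @param series a [measurement_series()].
#' @param path output file path.
#' @param units list with elements `time` and `activity` naming the units
#'   the file is written in; defaults to the internal s / Bq so that the
#'   round trip is exact.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path,
                         units = list(time = "s", activity = "Bq")) {
  stopifnot(inherits(series, "measurement_series"))
  sc <- unit_scale(units)
  src <- series$sources
  head_obj <- list(
    format = "deadtime-series", version = 1L,
    units = list(time = units$time, activity = units$activity),
    metadata = series$metadata,
    sources = lapply(seq_len(nrow(src)), function(i) list(
      source_id = src$source_id[i],
      reference_activity = src$reference_activity[i] / sc$activity,
      reference_time = src$reference_time[i] / sc$time,
      half_life = src$half_life[i] / sc$time)))
  hdr <- strsplit(yaml::as.yaml(head_obj, precision = 17), "\n")[[1]]
  m <- series$measurements
  body <- paste(m$detector_id, m$window,
                fmt_num(m$t_start / sc$time),
                fmt_num(m$duration / sc$time),
                fmt_num(m$counts), m$source_ids, sep = ",")
  writeLines(c("# ---", paste("#", hdr), "# ---",
               paste(SERIES_COLUMNS, collapse = ","), body), path)
  invisible(path)
}

#' Read a measurement series written by [write_series()]
#'
#' Units declared in the front matter are converted to the internal
#' seconds/Bq on read.  Malformed rows (wrong field count, non-numeric or
#' negative counts, non-positive durations) raise an error naming the
#' offending line.
#'
#' @param path input file path.
#' @return A [measurement_series()].
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# ---")
    stop("not a deadtime-series file (missing '# ---' front matter): ",
         path)
  end <- which(lines == "# ---")[2]
  if (is.na(end)) stop("unterminated front-matter block in ", path)
  hdr <- yaml::yaml.load(
    paste(sub("^# ?", "", lines[2:(end - 1)]), collapse = "\n"))
  if (!identical(hdr$format, "deadtime-series"))
    stop("unknown format declaration in ", path)
  sc <- unit_scale(hdr$units)
  src <- do.call(rbind, lapply(hdr$sources, function(s) data.frame(
    source_id = s$source_id,
    reference_activity = as.numeric(s$reference_activity) * sc$activity,
    reference_time = as.numeric(s$reference_time) * sc$time,
    half_life = as.numeric(s$half_life) * sc$time)))
  body <- lines[(end + 1):length(lines)]
  body_lineno <- (end + 1):length(lines)
  if (!length(body) || body[1] != paste(SERIES_COLUMNS, collapse = ","))
    stop("missing or wrong column header in ", path)
  rows <- body[-1]
  lineno <- body_lineno[-1]
  keep <- nzchar(trimws(rows))
  rows <- rows[keep]; lineno <- lineno[keep]
  parts <- strsplit(rows, ",", fixed = TRUE)
  m <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) == 5L) p <- c(p, "")  # empty trailing source_ids
    if (length(p) != 6L)
      stop("line ", lineno[i], ": expected 6 fields, got ", length(p))
    t_start <- suppressWarnings(as.numeric(p[3]))
    duration <- suppressWarnings(as.numeric(p[4]))
    counts <- suppressWarnings(as.numeric(p[5]))
    if (is.na(t_start) || is.na(duration) || is.na(counts))
      stop("line ", lineno[i], ": non-numeric t_start/duration/counts")
    if (!(duration > 0)) stop("line ", lineno[i], ": duration must be > 0")
    if (counts < 0) stop("line ", lineno[i], ": negative counts")
    data.frame(detector_id = p[1], window = p[2],
               t_start = t_start * sc$time, duration = duration * sc$time,
               counts = counts, source_ids = p[6])
  })
  measurement_series(do.call(rbind, m), src,
                     metadata = if (is.null(hdr$metadata)) list()
                                else hdr$metadata)
}

#' Write a fit report table as CSV with unit-suffixed columns
#'
#' @param report a data frame; columns named `tau`/`se_tau` (s),
#'   `sensitivity`/`se_sensitivity` (cps/Bq) and `total_activity` (Bq)
#'   are converted to us, kcps/MBq and MBq and renamed accordingly; every
#'   numeric column in the output carries its unit in the header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  conv <- list(tau = c("tau_us", 1e6), se_tau = c("se_tau_us", 1e6),
               sensitivity = c("sensitivity_kcps_per_MBq", 1e3),
               se_sensitivity = c("se_sensitivity_kcps_per_MBq", 1e3),
               total_activity = c("activity_MBq", 1e-6),
               r1 = c("r1_cps", 1), r2 = c("r2_cps", 1),
               r12 = c("r12_cps", 1), t_start = c("t_start_s", 1))
  for (nm in names(conv)) {
    if (nm %in% names(df)) {
      df[[nm]] <- df[[nm]] * as.numeric(conv[[nm]][2])
      names(df)[names(df) == nm] <- conv[[nm]][1]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
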