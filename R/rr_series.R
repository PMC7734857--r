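#' RR-interval series
#'
#' Container for one patient's sequence of RR intervals (the time between
#' consecutive heart beats). Beat onset times are derived as the cumulative
#' sum of the preceding intervals, so the first beat sits at time 0 and the
#' record ends at `sum(intervals) / 1000` seconds.
#'
#' @param intervals Numeric vector of RR intervals in milliseconds; all must
#'   be strictly positive and finite.
#' @param patient_id Identifier carried through all downstream tables.
#' @return An object of class `rr_series` with elements `patient_id`,
#'   `intervals` (ms) and `offsets` (beat onset times in seconds).
#' @examples
#' s <- rr_series(rep(1000, 10), patient_id = "p1")
#' rr_duration(s)  # 10 seconds
#' @export
rr_series <- function(intervals, patient_id = "patient") {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("no beats")
  if (anyNA(intervals) || any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("RR intervals must be positive finite numbers (milliseconds)")
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      intervals = intervals,
      offsets = cumsum(c(0, intervals[-length(intervals)])) / 1000
    ),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> patient %s: %d beats, %.2f h, mean RR %.1f ms\n",
    x$patient_id, length(x$intervals), rr_duration(x) / 3600,
    mean(x$intervals)
  ))
  invisible(x)
}

#' Total record duration in seconds
#'
#' @param series An [rr_series()].
#' @return Duration in seconds (sum of all intervals).
#' @export
rr_duration <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  sum(series$intervals) / 1000
}

#' Read an RR-interval series from a plain-text file
#'
#' Expects one RR interval in milliseconds per line; lines starting with `#`
#' are comments. This is the common export format of beat annotators.
#'
#' @param path File path.
#' @param patient_id Identifier for the series; defaults to the file name
#'   without extension.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, patient_id = NULL) {
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) stop("non-numeric RR values in ", path)
  rr_series(vals, patient_id = patient_id)
}

#' Write an RR-interval series to a plain-text file
#'
#' @param series An [rr_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  writeLines(
    c(sprintf("# patient_id: %s", series$patient_id),
      format(series$intervals, trim = TRUE, scientific = FALSE)),
    path
  )
  invisible(path)
}

#' Filter ectopic/artifact intervals
#'
#' Optional pre-filter removing intervals outside a physiological range or
#' differing from the previously accepted interval by more than a relative
#' threshold. Off by default in the pipeline: the acquisition protocol this
#' package models performed no artifact correction.
#'
#' @param series An [rr_series()].
#' @param range Acceptable RR range in ms (default 300--2000).
#' @param max_rel_diff Maximum relative jump from the previous accepted
#'   interval (default 0.2).
#' @return A filtered [rr_series()]; offsets are recomputed so the series
#'   remains contiguous.
#' @export
filter_artifacts <- function(series, range = c(300, 2000), max_rel_diff = 0.2) {
  stopifnot(inherits(series, "rr_series"))
  rr <- series$intervals
  keep <- logical(length(rr))
  last <- NA_real_
  for (k in seq_along(rr)) {
    ok <- rr[k] >= range[1] && rr[k] <= range[2] &&
      (is.na(last) || abs(rr[k] - last) / last <= max_rel_diff)
    keep[k] <- ok
    if (ok) last <- rr[k]
  }
  if (!any(keep)) stop("no beats survive artifact filtering")
  rr_series(rr[keep], patient_id = series$patient_id)
}
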