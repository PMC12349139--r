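#' Construct a triaxial accelerometer trial
#'
#' A trial is one continuous recording from a body-worn triaxial
#' accelerometer: an `L x 3` matrix of accelerations in m/s^2 (axes x, y, z)
#' together with its sampling rate, the subject who produced it, an activity
#' label, and optionally the sample intervals during which a fall occurred.
#'
#' Fall intervals use half-open, 0-based sample indexing: the interval
#' `(s, e)` covers samples `s, s+1, ..., e-1`. Intervals must be sorted and
#' non-overlapping.
#'
#' @param samples numeric matrix `L x 3`, acceleration in m/s^2.
#' @param rate_hz sampling rate in samples per second (positive).
#' @param subject_id subject identifier (scalar character).
#' @param activity free-text activity label, e.g. `"adl"` or `"fall_front"`.
#' @param fall_intervals list of length-2 integer vectors `c(start, end)`,
#'   half-open 0-based sample intervals marking fall events; may be empty.
#'
#' @return An object of class `fall_trial`.
#' @examples
#' tr <- trial(matrix(rnorm(30), 10, 3), rate_hz = 32, subject_id = "S1")
#' nrow(tr$samples)
#' @export
trial <- function(samples, rate_hz, subject_id = "unknown",
                  activity = "unknown", fall_intervals = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  obj <- structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         subject_id = as.character(subject_id),
         activity = as.character(activity),
         fall_intervals = lapply(fall_intervals, function(iv) as.integer(iv[1:2]))),
    class = "fall_trial")
  validate_trial(obj)
  obj
}

#' Validate a fall_trial's invariants
#'
#' Checks shape, finiteness and the fall-interval contract (half-open,
#' within bounds, sorted, non-overlapping). Called by [trial()] and by any
#' code that mutates a trial.
#'
#' @param x a `fall_trial`.
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_trial <- function(x) {
  stopifnot(inherits(x, "fall_trial"))
  L <- nrow(x$samples)
  if (is.null(L) || L < 1L) stop("trial must contain at least one sample")
  if (ncol(x$samples) != 3L) stop("trial samples must have exactly 3 axes")
  if (!all(is.finite(x$samples))) stop("trial contains non-finite samples")
  if (!is.finite(x$rate_hz) || x$rate_hz <= 0) stop("rate_hz must be positive")
  prev_end <- 0L
  for (iv in x$fall_intervals) {
    if (length(iv) != 2L || anyNA(iv)) stop("malformed fall interval")
    if (iv[1] >= iv[2]) stop("interval start >= end: (", iv[1], ",", iv[2], ")")
    if (iv[1] < 0L || iv[2] > L) stop("fall interval out of range")
    if (iv[1] < prev_end) stop("fall intervals overlap or are unsorted")
    prev_end <- iv[2]
  }
  invisible(x)
}

#' @export
print.fall_trial <- function(x, ...) {
  cat(sprintf("<fall_trial> subject=%s activity=%s L=%d @ %.6g Hz (%.2f s), %d fall interval(s)\n",
              x$subject_id, x$activity, nrow(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz, length(x$fall_intervals)))
  invisible(x)
}

label_path_for <- function(path) {
  sub("\\.csv$", ".labels.csv", path)
}

#' Read a trial from delimited text
#'
#' Reads a comma-delimited file with header `time,x,y,z` (time in seconds,
#' acceleration in m/s^2). If a sibling label file `<name>.labels.csv` with
#' columns `start,end` exists, its rows become the trial's fall intervals
#' (half-open 0-based sample indices). No normalization or outlier removal
#' is applied: downstream generators must see the raw signal, including the
#' extreme impact accelerations that characterise real falls.
#'
#' @param path path to the trial CSV.
#' @param rate_hz sampling rate of the recording.
#' @param subject_id subject identifier to attach.
#' @param activity activity label to attach.
#' @return A [trial()].
#' @export
read_trial <- function(path, rate_hz, subject_id = "unknown", activity = "unknown") {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("trial file ", path, " must have header columns time,x,y,z")
  }
  m <- as.matrix(df[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  bad <- which(!stats::complete.cases(m) | !apply(is.finite(m), 1, all))
  if (length(bad)) {
    stop("non-finite or malformed value in ", path, " at data line ", bad[1] + 1L)
  }
  intervals <- list()
  lp <- label_path_for(path)
  if (file.exists(lp)) {
    lab <- utils::read.csv(lp)
    if (!all(c("start", "end") %in% names(lab))) {
      stop("label file ", lp, " must have header columns start,end")
    }
    if (nrow(lab)) {
      for (i in seq_len(nrow(lab))) {
        s <- lab$start[i]; e <- lab$end[i]
        if (!is.finite(s) || !is.finite(e)) stop("label file ", lp, ": malformed row at line ", i + 1L)
        if (s >= e) stop("label file ", lp, " line ", i + 1L, ": interval start >= end")
        intervals[[length(intervals) + 1L]] <- c(as.integer(s), as.integer(e))
      }
    }
  }
  trial(m, rate_hz = rate_hz, subject_id = subject_id,
        activity = activity, fall_intervals = intervals)
}

#' Write a trial to delimited text
#'
#' Inverse of [read_trial()]: writes `time,x,y,z` rows (time derived from
#' `rate_hz`) and, when the trial carries fall intervals, a sibling
#' `<name>.labels.csv` with `start,end` columns.
#'
#' @param x a `fall_trial`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(x, path) {
  validate_trial(x)
  L <- nrow(x$samples)
  df <- data.frame(time = (seq_len(L) - 1L) / x$rate_hz,
                   x = x$samples[, 1], y = x$samples[, 2], z = x$samples[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  if (length(x$fall_intervals)) {
    lab <- data.frame(start = vapply(x$fall_intervals, function(iv) as.integer(iv[1]), integer(1)),
                      end   = vapply(x$fall_intervals, function(iv) as.integer(iv[2]), integer(1)))
    utils::write.csv(lab, label_path_for(path), row.names = FALSE)
  }
  invisible(path)
}
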