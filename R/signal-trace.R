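#' Construct a uniformly sampled physiological signal trace
#'
#' A `signal_trace` is one channel of a physiological recording sampled at a
#' fixed rate: either a photoplethysmogram (PPG, arbitrary units) or an
#' electrodermal activity channel (EDA, microsiemens). Sample `i` (1-based)
#' is located at `start_offset + (i - 1) / sampling_rate` seconds on the
#' session clock.
#'
#' @param samples numeric vector of amplitudes; must be finite and non-empty.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel `"PPG"` or `"EDA"`.
#' @param start_offset seconds from session start to the first sample
#'   (>= 0, default 0).
#' @return an object of class `signal_trace` with fields `samples`,
#'   `sampling_rate`, `channel`, `start_offset`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * (0:63) / 64), 64, "PPG")
#' trace_duration(tr)
#' @export
signal_trace <- function(samples, sampling_rate, channel = c("PPG", "EDA"),
                         start_offset = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("signal_trace: 'samples' must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop(sprintf("signal_trace: non-finite sample at position %d", bad),
         call. = FALSE)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("signal_trace: 'sampling_rate' must be a positive finite number",
         call. = FALSE)
  }
  if (!is.finite(start_offset) || start_offset < 0) {
    stop("signal_trace: 'start_offset' must be non-negative", call. = FALSE)
  }
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         channel = channel,
         start_offset = as.numeric(start_offset)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace %s: %d samples @ %g Hz, offset %g s, %.1f s>\n",
              x$channel, length(x$samples), x$sampling_rate,
              x$start_offset, trace_duration(x)))
  invisible(x)
}

#' Duration and timestamps of a trace
#'
#' @param trace a [signal_trace()].
#' @return `trace_duration`: duration in seconds (`n / rate`);
#'   `trace_times`: the session-clock timestamp of every sample.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  length(trace$samples) / trace$sampling_rate
}

#' @rdname trace_duration
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  trace$start_offset +
    (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Read a signal trace from CSV
#'
#' Two dialects are accepted. The single-column dialect has header `value`
#' (or no header) and one numeric amplitude per row; the sampling rate is
#' taken from the `sampling_rate` argument. The timestamped dialect has
#' header `time_s,value`; timestamps must be uniformly spaced to within
#' 1e-6 s and their implied rate must agree with the declared rate to within
#' 0.1%.
#'
#' @param path CSV file path.
#' @param channel `"PPG"` or `"EDA"`.
#' @param sampling_rate declared sampling rate in Hz.
#' @return a [signal_trace()].
#' @export
read_trace_csv <- function(path, channel = c("PPG", "EDA"), sampling_rate) {
  channel <- match.arg(channel)
  if (!file.exists(path)) {
    stop(sprintf("read_trace_csv: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("read_trace_csv: %s is empty", path), call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]]))
  timestamped <- identical(header, c("time_s", "value"))
  has_header <- timestamped || identical(header, "value")
  data_lines <- if (has_header) lines[-1L] else lines
  first_row <- if (has_header) 2L else 1L
  if (length(data_lines) == 0L) {
    stop(sprintf("read_trace_csv: %s has no data rows", path), call. = FALSE)
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  ncol_expect <- if (timestamped) 2L else 1L
  nc <- lengths(parts)
  if (any(nc != ncol_expect)) {
    bad <- which(nc != ncol_expect)[1L]
    stop(sprintf("read_trace_csv: row %d of %s has %d fields (expected %d)",
                 bad + first_row - 1L, path, nc[bad], ncol_expect),
         call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(trimws(unlist(parts)))),
                ncol = ncol_expect, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("read_trace_csv: non-numeric value at row %d of %s",
                 bad + first_row - 1L, path), call. = FALSE)
  }
  if (timestamped) {
    times <- mat[, 1L]
    values <- mat[, 2L]
    offset <- times[1L]
    if (length(times) > 1L) {
      dt <- diff(times)
      if (any(abs(dt - dt[1L]) > 1e-6)) {
        bad <- which(abs(dt - dt[1L]) > 1e-6)[1L]
        stop(sprintf(
          "read_trace_csv: non-uniform timestamps at row %d of %s",
          bad + first_row, path), call. = FALSE)
      }
      inferred <- 1 / mean(dt)
      if (abs(inferred - sampling_rate) / sampling_rate > 1e-3) {
        stop(sprintf(
          "read_trace_csv: declared rate %g Hz but timestamps imply %g Hz",
          sampling_rate, inferred), call. = FALSE)
      }
    }
    signal_trace(values, sampling_rate, channel, start_offset = offset)
  } else {
    signal_trace(mat[, 1L], sampling_rate, channel)
  }
}

#' Write a signal trace to CSV (timestamped dialect)
#'
#' Emits header `time_s,value` and one row per sample at full double
#' precision, so a write/read roundtrip is lossless.
#'
#' @param trace a [signal_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  if (length(trace$samples) == 0L) {
    stop("write_trace_csv: trace has no samples", call. = FALSE)
  }
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) {
                    stop(sprintf("write_trace_csv: cannot open %s: %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(paste(format(trace_times(trace), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(trace$samples, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Slice one scheduled phase out of a trace
#'
#' Keeps samples whose timestamps fall in the half-open interval
#' `[start_s, end_s)` of the requested phase; the returned trace's
#' `start_offset` is set to the phase start.
#'
#' @param trace a [signal_trace()].
#' @param schedule a [phase_schedule()].
#' @param phase one of `"BASELINE"`, `"TSST_P"`, `"TSST_S"`, `"TSST_A"`.
#' @return a [signal_trace()] restricted to the phase.
#' @export
slice_phase <- function(trace, schedule, phase) {
  stopifnot(inherits(trace, "signal_trace"))
  iv <- schedule_interval(schedule, phase)
  tt <- trace_times(trace)
  # half-open [start, end): tolerate representation error at the boundaries
  eps <- 1e-9 / trace$sampling_rate
  keep <- tt >= iv$start_s - eps & tt < iv$end_s - eps
  if (!any(keep)) {
    stop(sprintf("slice_phase: no samples fall inside phase %s", phase),
         call. = FALSE)
  }
  signal_trace(trace$samples[keep], trace$sampling_rate, trace$channel,
               start_offset = iv$start_s)
}
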