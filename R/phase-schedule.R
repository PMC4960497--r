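#' Phase labels of a TSST-structured session
#'
#' The session protocol is a 5-min seated baseline followed by the three
#' Trier Social Stress Test phases: anticipatory preparation (TSST-P),
#' oral speech (TSST-S), and mental arithmetic (TSST-A).
#' @keywords internal
PHASE_LEVELS <- c("BASELINE", "TSST_P", "TSST_S", "TSST_A")

#' Construct a phase schedule
#'
#' A schedule is an ordered set of labeled, pairwise non-overlapping time
#' intervals `[start_s, end_s)` on the session clock. Each phase label may
#' appear at most once.
#'
#' @param phase character vector of phase labels (see [PHASE_LEVELS]).
#' @param start_s,end_s interval bounds in seconds; `end_s > start_s`.
#' @return a data frame of class `phase_schedule`, sorted by `start_s`.
#' @examples
#' phase_schedule(c("BASELINE", "TSST_P", "TSST_S", "TSST_A"),
#'                c(0, 300, 600, 900), c(300, 600, 900, 1200))
#' @export
phase_schedule <- function(phase, start_s, end_s) {
  phase <- as.character(phase)
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  stopifnot(length(phase) == length(start_s),
            length(phase) == length(end_s))
  bad <- setdiff(phase, PHASE_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf("phase_schedule: unknown phase label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(phase)) {
    stop(sprintf("phase_schedule: duplicated phase: %s",
                 phase[duplicated(phase)][1L]), call. = FALSE)
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    stop("phase_schedule: non-finite interval bound", call. = FALSE)
  }
  if (any(end_s <= start_s)) {
    i <- which(end_s <= start_s)[1L]
    stop(sprintf("phase_schedule: interval %s has end (%g) <= start (%g)",
                 phase[i], end_s[i], start_s[i]), call. = FALSE)
  }
  ord <- order(start_s)
  df <- data.frame(phase = phase[ord], start_s = start_s[ord],
                   end_s = end_s[ord], stringsAsFactors = FALSE)
  if (nrow(df) > 1L) {
    overlap <- which(df$start_s[-1L] < df$end_s[-nrow(df)])
    if (length(overlap) > 0L) {
      i <- overlap[1L]
      stop(sprintf("phase_schedule: intervals %s [%g,%g) and %s [%g,%g) overlap",
                   df$phase[i], df$start_s[i], df$end_s[i],
                   df$phase[i + 1L], df$start_s[i + 1L], df$end_s[i + 1L]),
           call. = FALSE)
    }
  }
  class(df) <- c("phase_schedule", "data.frame")
  df
}

#' Look up one phase's interval in a schedule
#'
#' @param schedule a [phase_schedule()].
#' @param phase a phase label.
#' @return a list with `start_s` and `end_s`.
#' @export
schedule_interval <- function(schedule, phase) {
  stopifnot(inherits(schedule, "phase_schedule"))
  i <- match(phase, schedule$phase)
  if (is.na(i)) {
    stop(sprintf("phase %s is not present in the schedule", phase),
         call. = FALSE)
  }
  list(start_s = schedule$start_s[i], end_s = schedule$end_s[i])
}

#' Read / write a phase schedule CSV
#'
#' The schedule file has header `phase,start_s,end_s`, one row per phase.
#'
#' @param path CSV file path.
#' @return `read_schedule_csv`: a validated [phase_schedule()] sorted by
#'   start time.
#' @export
read_schedule_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_schedule_csv: file not found: %s", path),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_schedule_csv: %s must have columns %s",
                 path, paste(need, collapse = ",")), call. = FALSE)
  }
  phase_schedule(df$phase, df$start_s, df$end_s)
}

#' @rdname read_schedule_csv
#' @param schedule a [phase_schedule()] to write.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "phase_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Bundle one participant's recording into a session
#'
#' @param participant_id character scalar.
#' @param ppg PPG [signal_trace()].
#' @param eda EDA [signal_trace()].
#' @param schedule a [phase_schedule()]; every interval must lie within the
#'   time span of both traces.
#' @return an object of class `tsst_session`.
#' @export
tsst_session <- function(participant_id, ppg, eda, schedule) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            inherits(ppg, "signal_trace"), inherits(eda, "signal_trace"),
            inherits(schedule, "phase_schedule"))
  if (ppg$channel != "PPG") stop("tsst_session: 'ppg' must be a PPG trace")
  if (eda$channel != "EDA") stop("tsst_session: 'eda' must be an EDA trace")
  eps <- 1e-9
  for (tr in list(ppg, eda)) {
    span0 <- tr$start_offset
    span1 <- tr$start_offset + trace_duration(tr)
    if (any(schedule$start_s < span0 - eps) ||
        any(schedule$end_s > span1 + eps)) {
      stop(sprintf(
        "tsst_session: schedule extends outside the %s trace span [%g, %g]",
        tr$channel, span0, span1), call. = FALSE)
    }
  }
  structure(list(participant_id = participant_id, ppg = ppg, eda = eda,
                 schedule = schedule),
            class = "tsst_session")
}

#' @export
print.tsst_session <- function(x, ...) {
  cat(sprintf("<tsst_session %s: PPG %g Hz, EDA %g Hz, %d phases>\n",
              x$participant_id, x$ppg$sampling_rate, x$eda$sampling_rate,
              nrow(x$schedule)))
  invisible(x)
}

#' The standard TSST session schedule
#'
#' Baseline `[0, 300)`, TSST-P `[300, 600)`, TSST-S `[600, 900)`,
#' TSST-A `[900, 1200)` — four 5-minute phases.
#' @return a [phase_schedule()].
#' @export
standard_tsst_schedule <- function() {
  phase_schedule(PHASE_LEVELS, c(0, 300, 600, 900), c(300, 600, 900, 1200))
}
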