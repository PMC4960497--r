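# Beat detection and minute-block feature extraction.
#
# The detector locates the pulse upstroke on the PPG first derivative:
# central-difference derivative, candidate peaks above an adaptive threshold
# (0.5 x the rolling 10-s 90th percentile of the positive derivative), and a
# 0.25 s refractory period. Heart rate for a minute block is 60 / mean(IBI)
# over valid intervals; intervals implying < 40 or > 180 bpm are excluded,
# and a block with fewer than 40 valid intervals is discarded for HR.

IBI_BPM_MIN <- 40
IBI_BPM_MAX <- 180
MIN_VALID_IBI_PER_BLOCK <- 40L
BLOCK_SECONDS <- 60

#' Detect heartbeats on a PPG trace
#'
#' Derivative-based upstroke detector. The first derivative is computed by
#' central differences; candidate beats are local maxima of the derivative
#' that exceed an adaptive threshold equal to half the rolling 90th
#' percentile (10-s window, evaluated on a 1-s grid and interpolated) of the
#' positive derivative values; candidates falling within a 0.25 s refractory
#' period after an accepted beat are suppressed.
#'
#' @param ppg a PPG [signal_trace()] with rate >= 32 Hz, duration >= 2 s.
#' @param refractory_s refractory period in seconds (default 0.25).
#' @return an object of class `beat_series`: list with `beat_times`
#'   (strictly increasing session-clock seconds; may be empty).
#' @export
detect_beats <- function(ppg, refractory_s = 0.25) {
  stopifnot(inherits(ppg, "signal_trace"))
  if (ppg$channel != "PPG") {
    stop("detect_beats: trace channel must be PPG", call. = FALSE)
  }
  if (ppg$sampling_rate < 32) {
    stop("detect_beats: sampling rate must be >= 32 Hz", call. = FALSE)
  }
  if (trace_duration(ppg) < 2) {
    stop("detect_beats: trace shorter than 2 s", call. = FALSE)
  }
  x <- ppg$samples
  n <- length(x)
  fs <- ppg$sampling_rate
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * (fs / 2)

  if (!any(d > 0)) {
    return(structure(list(beat_times = numeric(0)), class = "beat_series"))
  }

  # rolling 90th percentile of positive derivative, 10-s window, 1-s grid
  win <- 10 * fs
  grid <- seq(1L, n, by = max(1L, as.integer(fs)))
  q <- vapply(grid, function(i) {
    lo <- max(1L, i - as.integer(win / 2))
    hi <- min(n, i + as.integer(win / 2))
    seg <- d[lo:hi]
    seg <- seg[seg > 0]
    if (length(seg) == 0L) Inf else stats::quantile(seg, 0.9, names = FALSE)
  }, numeric(1))
  finite_q <- q[is.finite(q)]
  q[!is.finite(q)] <- max(finite_q)
  thr <- 0.5 * stats::approx(grid, q, xout = seq_len(n), rule = 2)$y

  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n],
              FALSE)
  cand <- which(is_max & d > thr & d > 0)
  if (length(cand) == 0L) {
    return(structure(list(beat_times = numeric(0)), class = "beat_series"))
  }

  # greedy refractory suppression
  refr <- refractory_s * fs
  keep <- cand[1L]
  last <- cand[1L]
  for (i in cand[-1L]) {
    if (i - last > refr) {
      keep <- c(keep, i)
      last <- i
    }
  }
  beat_times <- ppg$start_offset + (keep - 1) / fs
  structure(list(beat_times = beat_times), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d beats>\n", length(x$beat_times)))
  invisible(x)
}

#' Physiological validity of an inter-beat interval
#'
#' An interval is valid when the heart rate it implies, `60 / duration`,
#' lies in `[40, 180]` bpm: rates strictly below 40 or strictly above 180
#' are excluded, the exact bounds are kept.
#'
#' @param duration interval duration(s) in seconds (> 0); vectorized.
#' @return logical vector, `TRUE` for valid intervals.
#' @examples
#' validate_ibis(c(0.8, 1.5, 1.6, 0.32))
#' @export
validate_ibis <- function(duration) {
  if (any(!is.finite(duration) | duration <= 0)) {
    stop("validate_ibis: durations must be positive", call. = FALSE)
  }
  bpm <- 60 / duration
  bpm >= IBI_BPM_MIN & bpm <= IBI_BPM_MAX
}

#' Inter-beat intervals from a beat series
#'
#' Interval `i` runs from beat `i` to beat `i + 1`; its onset is the time of
#' beat `i`. Every consecutive-beat interval is kept, with a validity flag
#' from [validate_ibis()]; an invalid interval does not break the pairing of
#' later beats.
#'
#' @param beats a `beat_series` with at least 2 beats.
#' @return an `ibi_series` data frame with columns `onset_s`, `duration_s`,
#'   `valid`.
#' @export
ibi_from_beats <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  bt <- beats$beat_times
  if (length(bt) < 2L) {
    stop("ibi_from_beats: need at least 2 beats", call. = FALSE)
  }
  dur <- diff(bt)
  df <- data.frame(onset_s = bt[-length(bt)], duration_s = dur,
                   valid = validate_ibis(dur))
  class(df) <- c("ibi_series", "data.frame")
  df
}

#' Heart rate from a mean inter-beat interval
#'
#' @param mean_ibi mean interval in seconds (> 0).
#' @return heart rate in beats per minute, `60 / mean_ibi`.
#' @export
hr_from_mean_ibi <- function(mean_ibi) {
  if (any(!is.finite(mean_ibi) | mean_ibi <= 0)) {
    stop("hr_from_mean_ibi: mean IBI must be positive", call. = FALSE)
  }
  60 / mean_ibi
}

#' Minute-block features for one phase of a session
#'
#' The phase is partitioned into consecutive non-overlapping 60-s windows
#' (a trailing partial window is dropped). Per window: valid inter-beat
#' intervals whose onset lies in the window are counted; with fewer than 40
#' the block is discarded for heart rate (`hr_valid = FALSE`, `mean_hr =
#' NA`), otherwise `mean_hr = 60 / mean(valid IBI durations)`. `mean_eda` is
#' the arithmetic mean of the window's raw EDA samples.
#'
#' @param session a [tsst_session()] whose traces are already at analysis
#'   rates.
#' @param phase phase label present in the session schedule.
#' @param ibis optional precomputed `ibi_series` for the whole session
#'   (avoids re-running beat detection per phase).
#' @return a `minute_blocks` data frame: `participant_id`, `phase`,
#'   `minute_index` (0-based within phase), `mean_hr`, `mean_eda`,
#'   `hr_valid`, `n_valid_ibi`.
#' @export
block_features <- function(session, phase, ibis = NULL) {
  stopifnot(inherits(session, "tsst_session"))
  iv <- schedule_interval(session$schedule, phase)
  n_min <- floor((iv$end_s - iv$start_s) / BLOCK_SECONDS)
  if (n_min == 0L) {
    return(empty_minute_blocks())
  }
  if (is.null(ibis)) {
    beats <- detect_beats(session$ppg)
    ibis <- if (length(beats$beat_times) >= 2L) ibi_from_beats(beats) else
      data.frame(onset_s = numeric(0), duration_s = numeric(0),
                 valid = logical(0))
  }
  eda_t <- trace_times(session$eda)
  eps <- 1e-9
  rows <- lapply(seq_len(n_min) - 1L, function(k) {
    w0 <- iv$start_s + k * BLOCK_SECONDS
    w1 <- w0 + BLOCK_SECONDS
    in_win <- ibis$onset_s >= w0 - eps & ibis$onset_s < w1 - eps
    vdur <- ibis$duration_s[in_win & ibis$valid]
    n_valid <- length(vdur)
    hr_valid <- n_valid >= MIN_VALID_IBI_PER_BLOCK
    mean_hr <- if (hr_valid) hr_from_mean_ibi(mean(vdur)) else NA_real_
    eda_in <- session$eda$samples[eda_t >= w0 - eps & eda_t < w1 - eps]
    mean_eda <- if (length(eda_in) > 0L) mean(eda_in) else NA_real_
    data.frame(participant_id = session$participant_id, phase = phase,
               minute_index = k, mean_hr = mean_hr, mean_eda = mean_eda,
               hr_valid = hr_valid, n_valid_ibi = n_valid,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("minute_blocks", "data.frame")
  df
}

empty_minute_blocks <- function() {
  df <- data.frame(participant_id = character(0), phase = character(0),
                   minute_index = integer(0), mean_hr = numeric(0),
                   mean_eda = numeric(0), hr_valid = logical(0),
                   n_valid_ibi = integer(0), stringsAsFactors = FALSE)
  class(df) <- c("minute_blocks", "data.frame")
  df
}

#' Minute-block features for every scheduled phase
#'
#' Runs beat detection once on the session PPG and computes
#' [block_features()] for each phase in the schedule.
#'
#' @param session a [tsst_session()].
#' @return a `minute_blocks` data frame covering all phases.
#' @export
session_block_features <- function(session) {
  stopifnot(inherits(session, "tsst_session"))
  beats <- detect_beats(session$ppg)
  ibis <- if (length(beats$beat_times) >= 2L) ibi_from_beats(beats) else
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               valid = logical(0))
  out <- lapply(session$schedule$phase, function(ph)
    block_features(session, ph, ibis = ibis))
  df <- do.call(rbind, out)
  class(df) <- c("minute_blocks", "data.frame")
  df
}

#' Per-participant resting baseline profile
#'
#' Averages the baseline-phase minute blocks: `baseline_hr` over blocks with
#' a valid heart rate, `baseline_eda` over blocks with a defined EDA mean.
#' Task features are later normalized by subtracting this profile.
#'
#' @param blocks a `minute_blocks` data frame, all rows `BASELINE` phase.
#' @return a `baseline_profile` list: `participant_id`, `baseline_hr`,
#'   `baseline_eda`, `n_hr_blocks`, `n_eda_blocks`.
#' @export
compute_baseline <- function(blocks) {
  stopifnot(inherits(blocks, "data.frame"), nrow(blocks) > 0L)
  if (!all(blocks$phase == "BASELINE")) {
    stop("compute_baseline: all blocks must be BASELINE phase",
         call. = FALSE)
  }
  pid <- unique(blocks$participant_id)
  if (length(pid) != 1L) {
    stop("compute_baseline: blocks mix participants", call. = FALSE)
  }
  hr_ok <- blocks$hr_valid & is.finite(blocks$mean_hr)
  eda_ok <- is.finite(blocks$mean_eda)
  if (!any(hr_ok) || !any(eda_ok)) {
    stop(sprintf(
      "compute_baseline: participant %s has no valid baseline block; exclude from analysis",
      pid), call. = FALSE)
  }
  structure(list(participant_id = pid,
                 baseline_hr = mean(blocks$mean_hr[hr_ok]),
                 baseline_eda = mean(blocks$mean_eda[eda_ok]),
                 n_hr_blocks = sum(hr_ok), n_eda_blocks = sum(eda_ok)),
            class = "baseline_profile")
}

#' Baseline-normalized feature vectors
#'
#' Subtracts the participant's baseline profile from each valid minute
#' block: `dhr = mean_hr - baseline_hr` (bpm), `deda = mean_eda -
#' baseline_eda` (microsiemens). Blocks without a valid heart rate or a
#' defined EDA mean contribute nothing.
#'
#' @param blocks a `minute_blocks` data frame for one participant.
#' @param profile the matching [compute_baseline()] profile.
#' @return a `feature_vectors` data frame: `participant_id`, `phase`,
#'   `minute_index`, `dhr`, `deda`.
#' @export
normalize_blocks <- function(blocks, profile) {
  stopifnot(inherits(blocks, "data.frame"),
            inherits(profile, "baseline_profile"))
  if (nrow(blocks) > 0L &&
      !all(blocks$participant_id == profile$participant_id)) {
    stop("normalize_blocks: participant_id mismatch between blocks and profile",
         call. = FALSE)
  }
  ok <- blocks$hr_valid & is.finite(blocks$mean_hr) &
    is.finite(blocks$mean_eda)
  df <- data.frame(participant_id = blocks$participant_id[ok],
                   phase = blocks$phase[ok],
                   minute_index = blocks$minute_index[ok],
                   dhr = blocks$mean_hr[ok] - profile$baseline_hr,
                   deda = blocks$mean_eda[ok] - profile$baseline_eda,
                   stringsAsFactors = FALSE)
  class(df) <- c("feature_vectors", "data.frame")
  df
}

#' Write / read the combined feature table
#'
#' Columns `participant_id,phase,minute_index,mean_hr,mean_eda,dhr,deda,
#' hr_valid,n_valid_ibi`; undefined values are empty fields. Blocks with no
#' feature vector (discarded HR) appear with empty `dhr`/`deda`.
#'
#' @param blocks a `minute_blocks` data frame (possibly several
#'   participants).
#' @param features the matching `feature_vectors` data frame.
#' @param path output CSV path.
#' @export
write_feature_csv <- function(blocks, features, path) {
  key_b <- paste(blocks$participant_id, blocks$phase, blocks$minute_index)
  key_f <- paste(features$participant_id, features$phase,
                 features$minute_index)
  m <- match(key_b, key_f)
  out <- data.frame(participant_id = blocks$participant_id,
                    phase = blocks$phase,
                    minute_index = blocks$minute_index,
                    mean_hr = blocks$mean_hr,
                    mean_eda = blocks$mean_eda,
                    dhr = features$dhr[m],
                    deda = features$deda[m],
                    hr_valid = blocks$hr_valid,
                    n_valid_ibi = blocks$n_valid_ibi,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @return `read_feature_csv`: the feature table as a data frame with the
#'   same columns.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_feature_csv: file not found: %s", path),
         call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}
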