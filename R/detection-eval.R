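# Signal-detection-theory accounting over classified minute blocks.
# A hit is a correctly identified stress block; a miss is a stress block
# classified non-stress; a false alarm is a non-stress block classified
# stress; a correct rejection is a non-stress block classified non-stress.

#' Tally signal-detection outcomes
#'
#' @param truth integer vector of ground-truth labels (1 = stress,
#'   0 = non-stress), one per minute block.
#' @param predicted integer vector of classifier decisions, same length.
#' @return a `confusion_counts` list: `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`.
#' @examples
#' count_outcomes(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
count_outcomes <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("count_outcomes: 'truth' and 'predicted' differ in length",
         call. = FALSE)
  }
  if (length(truth) == 0L) {
    stop("count_outcomes: empty input", call. = FALSE)
  }
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L))) {
    stop("count_outcomes: labels must be 0 or 1", call. = FALSE)
  }
  structure(list(
    hits = sum(truth == 1L & predicted == 1L),
    misses = sum(truth == 1L & predicted == 0L),
    false_alarms = sum(truth == 0L & predicted == 1L),
    correct_rejections = sum(truth == 0L & predicted == 0L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: H=%d M=%d FA=%d CR=%d>\n",
              x$hits, x$misses, x$false_alarms, x$correct_rejections))
  invisible(x)
}

#' Detection metrics from outcome counts
#'
#' Accuracy is (hits + correct rejections) over all classified blocks; hit
#' rate is hits over true stress blocks; false-alarm rate is false alarms
#' over true non-stress blocks. A rate whose denominator is zero is
#' undefined and reported as `NA`, never as 0.
#'
#' @param counts a [count_outcomes()] result.
#' @return a `detection_metrics` list: `accuracy`, `hit_rate`,
#'   `false_alarm_rate`.
#' @examples
#' compute_metrics(count_outcomes(rep(1, 10), rep(c(1, 0), c(8, 2))))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  h <- counts$hits; m <- counts$misses
  fa <- counts$false_alarms; cr <- counts$correct_rejections
  total <- h + m + fa + cr
  if (total == 0L) {
    stop("compute_metrics: no classified blocks", call. = FALSE)
  }
  structure(list(
    accuracy = (h + cr) / total,
    hit_rate = if (h + m > 0L) h / (h + m) else NA_real_,
    false_alarm_rate = if (fa + cr > 0L) fa / (fa + cr) else NA_real_
  ), class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("<detection_metrics: acc=%s hit=%s fa=%s>\n",
              fmt(x$accuracy), fmt(x$hit_rate), fmt(x$false_alarm_rate)))
  invisible(x)
}

#' Evaluate a model on labeled blocks
#'
#' Pools minute blocks across participants (the block-level accounting) and
#' additionally reports per-participant counts.
#'
#' @param model a `stress_model`.
#' @param samples a `labeled_samples` data frame.
#' @return an `evaluation_report` list: `counts`, `metrics`,
#'   `n_participants`, `per_participant` (data frame of counts and accuracy
#'   by participant).
#' @export
evaluate_model <- function(model, samples) {
  pred <- predict(model, samples)$label
  counts <- count_outcomes(samples$label, pred)
  per <- lapply(split(seq_len(nrow(samples)), samples$participant_id),
                function(ix) {
                  cc <- count_outcomes(samples$label[ix], pred[ix])
                  data.frame(participant_id = samples$participant_id[ix][1L],
                             hits = cc$hits, misses = cc$misses,
                             false_alarms = cc$false_alarms,
                             correct_rejections = cc$correct_rejections,
                             accuracy = compute_metrics(cc)$accuracy,
                             stringsAsFactors = FALSE)
                })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(counts = counts, metrics = compute_metrics(counts),
                 n_participants = length(unique(samples$participant_id)),
                 per_participant = per),
            class = "evaluation_report")
}

#' Write an evaluation report as JSON
#'
#' @param report an [evaluate_model()] result.
#' @param path JSON file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(
    counts = unclass(report$counts),
    metrics = unclass(report$metrics),
    n_participants = report$n_participants,
    per_participant = report$per_participant
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
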