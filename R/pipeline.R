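# Configuration-driven orchestration: simulate -> features -> train ->
# evaluate, with every constant recorded in a single flat config document
# that is serialized alongside each output artifact.

#' Pipeline configuration
#'
#' Collects every constant of the analysis. The analysis rates (PPG 64 Hz,
#' EDA 4 Hz), the 40-180 bpm inter-beat-interval validity bounds, and the
#' 40-valid-IBI minimum per minute block are fixed properties of the method;
#' they are carried in the config for audit purposes and validated, not
#' tunable. Split, training, and simulator parameters are free.
#'
#' @param train_fraction training fraction of the stratified split
#'   (default 0.75).
#' @param n_folds cross-validation folds (default 5).
#' @param epochs,l2,loss SGD hyperparameters (see [train_sgd()]).
#' @param seed master RNG seed for every stochastic step.
#' @param cohort_n simulated cohort size (default 20).
#' @param sim a [reactivity_config()] for the simulator.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(train_fraction = 0.75, n_folds = 5L,
                            epochs = 1000L, l2 = 1e-4, loss = "hinge",
                            seed = 1L, cohort_n = 20L,
                            sim = reactivity_config()) {
  stopifnot(inherits(sim, "reactivity_config"))
  structure(list(version = 1L,
                 ppg_hz = PPG_ANALYSIS_HZ, eda_hz = EDA_ANALYSIS_HZ,
                 ibi_bpm_min = IBI_BPM_MIN, ibi_bpm_max = IBI_BPM_MAX,
                 min_valid_ibi = MIN_VALID_IBI_PER_BLOCK,
                 train_fraction = train_fraction,
                 n_folds = as.integer(n_folds),
                 epochs = as.integer(epochs), l2 = l2, loss = loss,
                 seed = as.integer(seed), cohort_n = as.integer(cohort_n),
                 sim = sim),
            class = "pipeline_config")
}

#' Write / read a pipeline config document
#'
#' Flat `key: value` text document (one key per line, simulator keys
#' prefixed `sim_`) with a `version` field.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- config[setdiff(names(config), "sim")]
  sim <- unclass(config$sim)
  names(sim) <- paste0("sim_", names(sim))
  kv <- c(flat, sim)
  writeLines(paste0(names(kv), ": ",
                    vapply(kv, format, character(1), digits = 17)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_config: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- which(lengths(m) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("read_config: malformed line %d: %s", bad[1L],
                 lines[bad[1L]]), call. = FALSE)
  }
  keys <- vapply(m, `[`, character(1), 2L)
  vals <- vapply(m, `[`, character(1), 3L)
  num <- suppressWarnings(as.numeric(vals))
  kv <- lapply(seq_along(vals), function(i)
    if (is.na(num[i])) vals[i] else num[i])
  names(kv) <- keys
  sim_keys <- grep("^sim_", keys, value = TRUE)
  sim_args <- kv[sim_keys]
  names(sim_args) <- sub("^sim_", "", sim_keys)
  cfg <- pipeline_config(
    train_fraction = kv$train_fraction %||% 0.75,
    n_folds = kv$n_folds %||% 5L,
    epochs = kv$epochs %||% 1000L,
    l2 = kv$l2 %||% 1e-4,
    loss = kv$loss %||% "hinge",
    seed = kv$seed %||% 1L,
    cohort_n = kv$cohort_n %||% 20L,
    sim = do.call(reactivity_config, sim_args))
  fixed <- c(ppg_hz = PPG_ANALYSIS_HZ, eda_hz = EDA_ANALYSIS_HZ,
             ibi_bpm_min = IBI_BPM_MIN, ibi_bpm_max = IBI_BPM_MAX,
             min_valid_ibi = MIN_VALID_IBI_PER_BLOCK)
  for (f in names(fixed)) {
    if (!is.null(kv[[f]]) && kv[[f]] != fixed[[f]]) {
      stop(sprintf(
        "read_config: %s is a fixed analysis constant (%g); refusing override (%g)",
        f, fixed[[f]], kv[[f]]), call. = FALSE)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Simulate a cohort and write it as a plain-text dataset
#'
#' Writes, into `out_dir`: one `<id>_ppg.csv` and `<id>_eda.csv` per
#' participant (timestamped trace dialect), a shared `schedule.csv`, a
#' `ground_truth.json`, and the effective `config.txt`.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$cohort_n, config$sim,
                            master_seed = config$seed)
  for (p in cohort) {
    id <- p$session$participant_id
    write_trace_csv(p$session$ppg, file.path(out_dir, paste0(id, "_ppg.csv")))
    write_trace_csv(p$session$eda, file.path(out_dir, paste0(id, "_eda.csv")))
  }
  write_schedule_csv(cohort[[1L]]$session$schedule,
                     file.path(out_dir, "schedule.csv"))
  truths <- lapply(cohort, function(p) unclass(p$truth))
  jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(out_dir, "config.txt"))
  .log("INFO", "simulated %d participants into %s", length(cohort), out_dir)
  invisible(out_dir)
}

# One participant's CSVs -> normalized feature rows; NULL when the
# participant has no usable baseline block.
.participant_features <- function(id, ppg_path, eda_path, schedule, config) {
  ppg <- resample_trace(read_trace_csv(ppg_path, "PPG",
                                       infer_rate_csv(ppg_path)),
                        config$ppg_hz)
  eda <- resample_trace(read_trace_csv(eda_path, "EDA",
                                       infer_rate_csv(eda_path)),
                        config$eda_hz)
  session <- tsst_session(id, ppg, eda, schedule)
  blocks <- session_block_features(session)
  base_blocks <- blocks[blocks$phase == "BASELINE", , drop = FALSE]
  profile <- tryCatch(compute_baseline(base_blocks), error = function(e) e)
  if (inherits(profile, "error")) {
    .log("WARN", "participant %s skipped: %s", id, conditionMessage(profile))
    return(NULL)
  }
  n_discard <- sum(!blocks$hr_valid)
  .log("INFO", "participant %s: %d blocks, %d HR-discarded", id,
       nrow(blocks), n_discard)
  list(blocks = blocks, features = normalize_blocks(blocks, profile))
}

#' Infer the sampling rate of a timestamped trace CSV
#'
#' Reads the first few rows of a `time_s,value` file and returns the implied
#' rate; errors for the single-column dialect (rate cannot be inferred).
#'
#' @param path trace CSV path.
#' @return sampling rate in Hz.
#' @export
infer_rate_csv <- function(path) {
  head_lines <- readLines(path, n = 4L, warn = FALSE)
  if (length(head_lines) < 3L ||
      tolower(trimws(head_lines[1L])) != "time_s,value") {
    stop(sprintf(
      "infer_rate_csv: %s is not a timestamped trace (pass the rate explicitly)",
      path), call. = FALSE)
  }
  t <- vapply(strsplit(head_lines[2:3], ","), function(p)
    as.numeric(p[1L]), numeric(1))
  1 / diff(t)
}

#' Extract minute-block features for every participant in a dataset
#'
#' Expects the [run_simulate()] file layout: `<id>_ppg.csv`,
#' `<id>_eda.csv`, `schedule.csv`. Traces are resampled to the analysis
#' rates (64 Hz PPG, 4 Hz EDA) when recorded faster, beats detected, minute
#' blocks computed, and features baseline-normalized per participant.
#' Participants without a valid baseline block are skipped with a logged
#' reason.
#'
#' @param in_dir dataset directory.
#' @param out_path output feature CSV path.
#' @param config a [pipeline_config()].
#' @return list with `path`, `n_participants`, `skipped` (ids), invisibly.
#' @export
run_features <- function(in_dir, out_path, config = pipeline_config()) {
  schedule <- read_schedule_csv(file.path(in_dir, "schedule.csv"))
  ppg_files <- sort(list.files(in_dir, "_ppg\\.csv$", full.names = TRUE))
  if (length(ppg_files) == 0L) {
    stop(sprintf("run_features: no *_ppg.csv files in %s", in_dir),
         call. = FALSE)
  }
  ids <- sub("_ppg\\.csv$", "", basename(ppg_files))
  all_blocks <- list(); all_feats <- list(); skipped <- character(0)
  for (i in seq_along(ids)) {
    eda_path <- file.path(in_dir, paste0(ids[i], "_eda.csv"))
    if (!file.exists(eda_path)) {
      stop(sprintf("run_features: missing EDA trace for participant %s",
                   ids[i]), call. = FALSE)
    }
    res <- .participant_features(ids[i], ppg_files[i], eda_path, schedule,
                                 config)
    if (is.null(res)) {
      skipped <- c(skipped, ids[i])
    } else {
      all_blocks[[ids[i]]] <- res$blocks
      all_feats[[ids[i]]] <- res$features
    }
  }
  if (length(all_feats) == 0L) {
    stop("run_features: every participant was skipped", call. = FALSE)
  }
  blocks <- do.call(rbind, all_blocks)
  feats <- do.call(rbind, all_feats)
  write_feature_csv(blocks, feats, out_path)
  write_config(config, paste0(out_path, ".config.txt"))
  invisible(list(path = out_path, n_participants = length(all_feats),
                 skipped = skipped))
}

.features_from_table <- function(path) {
  tab <- read_feature_csv(path)
  ok <- is.finite(tab$dhr) & is.finite(tab$deda)
  df <- tab[ok, c("participant_id", "phase", "minute_index", "dhr", "deda")]
  rownames(df) <- NULL
  class(df) <- c("feature_vectors", "data.frame")
  df
}

#' Train the stress classifier from a feature table
#'
#' Labels baseline vs. TSST-S blocks, makes the stratified 75:25 split,
#' trains the SGD model on the training portion, and writes the model JSON
#' plus a training report with train/test detection metrics.
#'
#' @param features_path feature CSV from [run_features()].
#' @param model_path output model JSON path.
#' @param config a [pipeline_config()].
#' @return list with `model`, `train_metrics`, `test_metrics`, invisibly.
#' @export
run_train <- function(features_path, model_path,
                      config = pipeline_config()) {
  samples <- label_blocks(.features_from_table(features_path),
                          include_tsst_a = FALSE)
  split <- split_dataset(samples, config$train_fraction, seed = config$seed)
  model <- train_sgd(split$train, seed = config$seed,
                     epochs = config$epochs, l2 = config$l2,
                     loss = config$loss)
  train_rep <- evaluate_model(model, split$train)
  test_rep <- if (nrow(split$test) > 0L) evaluate_model(model, split$test)
  write_model_json(model, model_path)
  write_config(config, paste0(model_path, ".config.txt"))
  rep_obj <- list(
    train = list(counts = unclass(train_rep$counts),
                 metrics = unclass(train_rep$metrics)),
    test = if (!is.null(test_rep))
      list(counts = unclass(test_rep$counts),
           metrics = unclass(test_rep$metrics)))
  jsonlite::write_json(rep_obj, paste0(model_path, ".train_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  .log("INFO", "train accuracy %.3f; test accuracy %s",
       train_rep$metrics$accuracy,
       if (is.null(test_rep)) "n/a" else
         sprintf("%.3f", test_rep$metrics$accuracy))
  invisible(list(model = model, train_metrics = train_rep$metrics,
                 test_metrics = if (!is.null(test_rep)) test_rep$metrics))
}

#' Cross-validate the classifier from a feature table
#'
#' @param features_path feature CSV from [run_features()].
#' @param out_path output JSON path (optional).
#' @param config a [pipeline_config()].
#' @return the `cv_result`, invisibly.
#' @export
run_cv <- function(features_path, out_path = NULL,
                   config = pipeline_config()) {
  samples <- label_blocks(.features_from_table(features_path),
                          include_tsst_a = FALSE)
  split <- split_dataset(samples, config$train_fraction, seed = config$seed)
  cv <- cross_validate(split$train, n_folds = config$n_folds,
                       seed = config$seed, epochs = config$epochs,
                       l2 = config$l2, loss = config$loss)
  if (!is.null(out_path)) {
    jsonlite::write_json(list(fold_accuracies = cv$fold_accuracies,
                              mean_accuracy = cv$mean_accuracy),
                         out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  .log("INFO", "cross-validation mean accuracy %.3f", cv$mean_accuracy)
  invisible(cv)
}

#' Evaluate a trained model on a feature table
#'
#' Labels blocks including the TSST-A phase as stress (held-out evaluation)
#' and writes the signal-detection report.
#'
#' @param features_path feature CSV from [run_features()].
#' @param model_path model JSON from [run_train()].
#' @param report_path output report JSON path.
#' @param include_tsst_a include arithmetic-task blocks as stress
#'   (default `TRUE`).
#' @param config a [pipeline_config()].
#' @return the `evaluation_report`, invisibly.
#' @export
run_evaluate <- function(features_path, model_path, report_path,
                         include_tsst_a = TRUE,
                         config = pipeline_config()) {
  samples <- label_blocks(.features_from_table(features_path),
                          include_tsst_a = include_tsst_a)
  model <- read_model_json(model_path)
  report <- evaluate_model(model, samples)
  write_report_json(report, report_path)
  write_config(config, paste0(report_path, ".config.txt"))
  .log("INFO", "evaluation accuracy %.3f (hit %.3f, FA %.3f) on %d blocks",
       report$metrics$accuracy, report$metrics$hit_rate,
       report$metrics$false_alarm_rate,
       with(report$counts, hits + misses + false_alarms + correct_rejections))
  invisible(report)
}

#' Classify every feature row with a trained model
#'
#' @param features_path feature CSV from [run_features()].
#' @param model_path model JSON.
#' @param out_path output CSV (`participant_id,phase,minute_index,score,label`).
#' @return the predictions data frame, invisibly.
#' @export
run_classify <- function(features_path, model_path, out_path) {
  feats <- .features_from_table(features_path)
  model <- read_model_json(model_path)
  pred <- predict(model, feats)
  out <- cbind(feats[, c("participant_id", "phase", "minute_index")], pred)
  utils::write.csv(out, out_path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
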