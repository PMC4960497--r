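# Shared fixtures, built in code at test time.

# Minimal single-phase session with a flat PPG and constant EDA; used with
# a hand-crafted IBI series to exercise the block rules in isolation.
flat_session <- function(duration_s = 61, eda_level = 4.0) {
  ppg <- signal_trace(rep(0, 64 * duration_s), 64, "PPG")
  eda <- signal_trace(rep(eda_level, 4 * duration_s), 4, "EDA")
  tsst_session("T01", ppg, eda,
               phase_schedule("BASELINE", 0, duration_s))
}

# IBI series with a chosen number of valid intervals inside [0, 60).
crafted_ibis <- function(n_valid, duration_s = 0.8, n_invalid = 0) {
  onset <- seq(0.1, by = duration_s, length.out = n_valid)
  df <- data.frame(onset_s = onset,
                   duration_s = rep(duration_s, n_valid),
                   valid = rep(TRUE, n_valid))
  if (n_invalid > 0) {
    bad <- data.frame(onset_s = seq(0.15, by = duration_s,
                                    length.out = n_invalid),
                      duration_s = 1.6, valid = FALSE)
    df <- rbind(df, bad)
    df <- df[order(df$onset_s), ]
  }
  df
}

# Cohort -> pooled normalized feature vectors (the standard pipeline head).
cohort_features <- function(cohort) {
  out <- lapply(cohort, function(p) {
    b <- session_block_features(p$session)
    prof <- compute_baseline(b[b$phase == "BASELINE", , drop = FALSE])
    normalize_blocks(b, prof)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("feature_vectors", "data.frame")
  df
}

# Two well-separated Gaussian clusters as labeled samples.
separable_samples <- function(n_per_class = 50, seed = 99, spread = 0.05) {
  set.seed(seed)
  data.frame(
    participant_id = "X",
    phase = rep(c("BASELINE", "TSST_S"), each = n_per_class),
    minute_index = seq_len(2 * n_per_class),
    dhr = c(rnorm(n_per_class, -1, spread), rnorm(n_per_class, 1, spread)),
    deda = c(rnorm(n_per_class, -1, spread), rnorm(n_per_class, 1, spread)),
    label = rep(c(0L, 1L), each = n_per_class),
    stringsAsFactors = FALSE)
}

# Independent brute-force recount of signal-detection outcomes (loop-based
# oracle, deliberately naive).
oracle_counts <- function(truth, predicted) {
  h <- m <- fa <- cr <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1L) {
      if (predicted[i] == 1L) h <- h + 1L else m <- m + 1L
    } else {
      if (predicted[i] == 1L) fa <- fa + 1L else cr <- cr + 1L
    }
  }
  list(hits = h, misses = m, false_alarms = fa, correct_rejections = cr)
}
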