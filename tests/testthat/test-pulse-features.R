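test_that("detect_beats recovers a clean pulse train and handles edge inputs", {
  sim <- simulate_ppg(rep(60, 2), jitter_cv = 0, seed = 5)  # 120 s @ 64 Hz
  beats <- detect_beats(sim$trace)
  expect_lte(abs(length(beats$beat_times) - 120), 1)
  expect_equal(length(beats$beat_times), length(sim$beat_times))
  expect_lt(max(abs(beats$beat_times - sim$beat_times)), 1 / 64 + 1e-9)

  flat <- signal_trace(rep(0, 64 * 60), 64, "PPG")
  expect_length(detect_beats(flat)$beat_times, 0)

  # single pulse in an otherwise flat trace
  x <- rep(0, 64 * 30)
  tpulse <- (0:63) / 64
  x[64 * 15 + 1:64] <- 0.5 * (1 - cos(pi * pmin(tpulse / 0.12, 1)))
  one <- detect_beats(signal_trace(x, 64, "PPG"))
  expect_length(one$beat_times, 1)

  expect_error(detect_beats(signal_trace(rep(0, 640), 4, "EDA")), "PPG")
  expect_error(detect_beats(signal_trace(rep(0, 16), 16, "PPG")), "32 Hz")
  expect_error(detect_beats(signal_trace(rep(0, 64), 64, "PPG")),
               "shorter than 2 s")
})

test_that("IBI validity applies the 40-180 bpm rule with kept boundaries", {
  expect_equal(validate_ibis(c(0.8, 1.5, 1.6, 0.32, 60 / 180, 0.30)),
               c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_error(validate_ibis(c(0.8, 0)), "positive")
  expect_error(validate_ibis(-1), "positive")
})

test_that("ibi_from_beats pairs consecutive beats and flags validity", {
  b <- structure(list(beat_times = c(0, 1, 2, 3)), class = "beat_series")
  ib <- ibi_from_beats(b)
  expect_equal(ib$duration_s, rep(1, 3))
  expect_equal(ib$onset_s, c(0, 1, 2))
  expect_true(all(ib$valid))
  slow <- ibi_from_beats(structure(list(beat_times = c(0, 1.6)),
                                   class = "beat_series"))
  expect_false(slow$valid)       # 37.5 bpm
  fast <- ibi_from_beats(structure(list(beat_times = c(0, 0.30)),
                                   class = "beat_series"))
  expect_false(fast$valid)       # 200 bpm
  expect_error(ibi_from_beats(structure(list(beat_times = 1),
                                        class = "beat_series")),
               "at least 2")
})

test_that("hr_from_mean_ibi is 60 over the mean interval", {
  expect_equal(hr_from_mean_ibi(c(1.0, 0.5, 0.75)), c(60, 120, 80))
  expect_error(hr_from_mean_ibi(0), "positive")
})

test_that("minute blocks apply the 40-valid-IBI discard rule exactly", {
  sess <- flat_session()
  b39 <- block_features(sess, "BASELINE", ibis = crafted_ibis(39))
  expect_false(b39$hr_valid)
  expect_true(is.na(b39$mean_hr))
  expect_equal(b39$n_valid_ibi, 39)
  b40 <- block_features(sess, "BASELINE", ibis = crafted_ibis(40))
  expect_true(b40$hr_valid)
  expect_equal(b40$mean_hr, 60 / 0.8)
  # invalid intervals do not count toward the 40
  b_mix <- block_features(sess, "BASELINE",
                          ibis = crafted_ibis(39, n_invalid = 10))
  expect_false(b_mix$hr_valid)
  # 75 valid IBIs of 0.8 s -> 75 bpm; constant EDA 4.0 -> mean 4.0
  b75 <- block_features(sess, "BASELINE", ibis = crafted_ibis(75))
  expect_equal(b75$mean_hr, 75)
  expect_equal(b75$mean_eda, 4.0)
})

test_that("phases partition into complete minutes, trailing partials dropped", {
  sim <- simulate_session("P01", seed = 21)
  blocks <- session_block_features(sim$session)
  counts <- table(blocks$phase)
  expect_true(all(counts == 5))          # 5 complete minutes per 300-s phase
  expect_equal(nrow(blocks), 20)
  expect_equal(sort(unique(blocks$minute_index)), 0:4)
  # 90-s phase -> 1 block; 45-s phase -> none
  short <- tsst_session("S", signal_trace(rep(0, 64 * 90), 64, "PPG"),
                        signal_trace(rep(1, 4 * 90), 4, "EDA"),
                        phase_schedule("TSST_S", 0, 90))
  expect_equal(nrow(block_features(short, "TSST_S",
                                   ibis = crafted_ibis(0, 0.8))), 1)
  tiny <- tsst_session("S", signal_trace(rep(0, 64 * 45), 64, "PPG"),
                       signal_trace(rep(1, 4 * 45), 4, "EDA"),
                       phase_schedule("TSST_S", 0, 45))
  expect_equal(nrow(block_features(tiny, "TSST_S",
                                   ibis = crafted_ibis(0, 0.8))), 0)
})

test_that("block mean HR tracks the simulator's programmed trajectory", {
  sim <- simulate_session("P02", seed = 31)
  blocks <- session_block_features(sim$session)
  per_min_hr <- blocks$mean_hr[order(match(blocks$phase, sim$session$schedule$phase),
                                     blocks$minute_index)]
  expect_true(all(abs(per_min_hr - sim$truth$hr_per_minute) < 2))
  # determinism of the extraction
  blocks2 <- session_block_features(sim$session)
  expect_identical(blocks, blocks2)
})

test_that("baseline profile and normalization behave as stated", {
  hr <- c(70, 72, 68, 71, 69)
  blocks <- data.frame(participant_id = "Q", phase = "BASELINE",
                       minute_index = 0:4, mean_hr = hr,
                       mean_eda = c(4, 4.2, 3.8, 4.1, 3.9),
                       hr_valid = TRUE, n_valid_ibi = 60L)
  prof <- compute_baseline(blocks)
  expect_equal(prof$baseline_hr, 70)
  expect_equal(prof$baseline_eda, 4)
  one <- compute_baseline(blocks[3, ])
  expect_equal(one$baseline_hr, 68)
  none <- transform(blocks, hr_valid = FALSE, mean_hr = NA_real_)
  expect_error(compute_baseline(none), "no valid baseline")
  expect_error(compute_baseline(transform(blocks, phase = "TSST_S")),
               "BASELINE")

  fv <- normalize_blocks(blocks, prof)
  expect_equal(mean(fv$dhr), 0, tolerance = 1e-9)   # self-normalization
  expect_equal(mean(fv$deda), 0, tolerance = 1e-9)
  task <- data.frame(participant_id = "Q", phase = "TSST_S",
                     minute_index = 0L, mean_hr = 85, mean_eda = 6.5,
                     hr_valid = TRUE, n_valid_ibi = 70L)
  tv <- normalize_blocks(task, prof)
  expect_equal(tv$dhr, 15)
  expect_equal(tv$deda, 6.5 - 4)
  # invalid blocks are skipped; participant mismatch errors
  task$hr_valid <- FALSE
  expect_equal(nrow(normalize_blocks(task, prof)), 0)
  task$participant_id <- "R"
  task$hr_valid <- TRUE
  expect_error(normalize_blocks(task, prof), "mismatch")
})

test_that("feature table CSV roundtrips with empty undefined fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  blocks <- rbind(
    data.frame(participant_id = "Q", phase = "BASELINE", minute_index = 0L,
               mean_hr = 70, mean_eda = 4, hr_valid = TRUE,
               n_valid_ibi = 60L),
    data.frame(participant_id = "Q", phase = "TSST_S", minute_index = 0L,
               mean_hr = NA_real_, mean_eda = 5, hr_valid = FALSE,
               n_valid_ibi = 12L))
  prof <- compute_baseline(blocks[1, ])
  fv <- normalize_blocks(blocks, prof)
  write_feature_csv(blocks, fv, path)
  header <- readLines(path, n = 1)
  expect_equal(header,
    "participant_id,phase,minute_index,mean_hr,mean_eda,dhr,deda,hr_valid,n_valid_ibi")
  back <- read_feature_csv(path)
  expect_equal(nrow(back), 2)
  expect_true(is.na(back$mean_hr[2]) && is.na(back$dhr[2]))
  expect_equal(back$mean_hr[1], 70)
})
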