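test_that("signal_trace validates its invariants", {
  tr <- signal_trace(c(1, 2, 3), 4, "PPG")
  expect_equal(trace_duration(tr), 0.75)
  expect_equal(trace_times(tr), c(0, 0.25, 0.5))
  expect_error(signal_trace(numeric(0), 4, "PPG"), "non-empty")
  expect_error(signal_trace(c(1, NA, 3), 4, "PPG"), "position 2")
  expect_error(signal_trace(c(1, Inf), 4, "PPG"), "non-finite")
  expect_error(signal_trace(1:3, 0, "PPG"), "positive")
  expect_error(signal_trace(1:3, 4, "PPG", start_offset = -1),
               "non-negative")
})

test_that("trace CSV roundtrip is lossless in both dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  # single-column dialect
  writeLines(c("value", "1.0", "2.0", "3.0"), path)
  tr <- read_trace_csv(path, "PPG", sampling_rate = 4)
  expect_equal(tr$samples, c(1, 2, 3))
  expect_equal(trace_duration(tr), 0.75)
  # timestamped roundtrip, irrational-looking values and offset
  orig <- signal_trace(sin(1:50) * pi, 64, "EDA", start_offset = 2.5)
  write_trace_csv(orig, path)
  back <- read_trace_csv(path, "EDA", 64)
  expect_equal(back$samples, orig$samples, tolerance = 1e-12)
  expect_equal(back$start_offset, orig$start_offset)
  expect_equal(back$sampling_rate, orig$sampling_rate)
})

test_that("trace CSV errors carry row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("value", "1.0", "abc", "3.0"), path)
  expect_error(read_trace_csv(path, "PPG", 4), "row 3")
  writeLines(c("time_s,value", "0,1", "0.25,2", "0.6,3"), path)
  expect_error(read_trace_csv(path, "PPG", 4), "non-uniform")
  writeLines(c("time_s,value", "0,1", "0.25,2", "0.5,3"), path)
  expect_error(read_trace_csv(path, "PPG", 10), "declared rate")
  expect_error(read_trace_csv(file.path(tempdir(), "nope.csv"), "PPG", 4),
               "not found")
  expect_error(write_trace_csv(signal_trace(1, 4, "PPG"),
                               file.path(tempdir(), "no/such/dir/x.csv")),
               "cannot open")
})

test_that("schedule CSV reads, sorts, and rejects overlap", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("phase,start_s,end_s",
               "TSST_S,600,900", "BASELINE,0,300",
               "TSST_A,900,1200", "TSST_P,300,600"), path)
  sch <- read_schedule_csv(path)
  expect_equal(sch$phase, c("BASELINE", "TSST_P", "TSST_S", "TSST_A"))
  expect_equal(sch$start_s, c(0, 300, 600, 900))
  expect_error(phase_schedule(c("BASELINE", "TSST_P"), c(0, 200),
                              c(300, 500)),
               "BASELINE \\[0,300\\) and TSST_P \\[200,500\\) overlap")
  expect_error(phase_schedule("TSST_S", 300, 300), "end \\(300\\)")
  expect_error(phase_schedule("LUNCH", 0, 10), "unknown phase")
  expect_error(phase_schedule(c("TSST_S", "TSST_S"), c(0, 400), c(300, 700)),
               "duplicated")
})

test_that("resample_trace preserves DC exactly and is a no-op at own rate", {
  tr <- signal_trace(rep(5, 3000), 1000, "EDA")
  out <- resample_trace(tr, 4)
  expect_equal(length(out$samples), round(3000 * 4 / 1000))
  expect_true(all(abs(out$samples - 5) < 1e-6))
  same <- resample_trace(tr, 1000)
  expect_identical(same$samples, tr$samples)
  expect_error(resample_trace(tr, -1), "positive")
})

test_that("resampled sinusoid matches the closed form", {
  # 1 Hz sinusoid, 1000 Hz, 30 s -> 64 Hz; compare to the analytic signal
  t <- (0:29999) / 1000
  tr <- signal_trace(sin(2 * pi * t), 1000, "PPG")
  out <- resample_trace(tr, 64)
  expect_equal(length(out$samples), round(30000 * 64 / 1000))
  tt <- trace_times(out)
  inner <- tt > 2 & tt < 28   # exclude filter edge transients
  err <- max(abs(out$samples[inner] - sin(2 * pi * tt[inner])))
  expect_lt(err, 0.01)
  # mean preservation for band-limited content
  expect_equal(mean(out$samples), mean(tr$samples), tolerance = 0.01)
})

test_that("slice_phase uses half-open windows and partitions the session", {
  sch <- standard_tsst_schedule()
  tr <- signal_trace(seq_len(4 * 1200), 4, "EDA")
  base <- slice_phase(tr, sch, "BASELINE")
  expect_equal(length(base$samples), 1200)   # 300 s x 4 Hz
  expect_equal(base$start_offset, 0)
  # sample at exactly end_s is excluded from the earlier phase
  s2 <- slice_phase(tr, sch, "TSST_P")
  expect_equal(s2$samples[1], tr$samples[300 * 4 + 1])
  # full partition reconstructs the original count
  n_total <- sum(vapply(sch$phase, function(p)
    length(slice_phase(tr, sch, p)$samples), numeric(1)))
  expect_equal(n_total, length(tr$samples))
  expect_error(slice_phase(tr, phase_schedule("BASELINE", 0, 300), "TSST_S"),
               "not present")
})

test_that("tsst_session rejects schedules outside the trace span", {
  ppg <- signal_trace(rep(0, 64 * 100), 64, "PPG")
  eda <- signal_trace(rep(1, 4 * 1200), 4, "EDA")
  expect_error(tsst_session("A", ppg, eda, standard_tsst_schedule()),
               "outside the PPG trace span")
  expect_error(tsst_session("A", eda, eda, standard_tsst_schedule()),
               "must be a PPG trace")
})
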