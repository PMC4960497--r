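test_that("label_blocks applies the phase-derived ground truth", {
  fv <- data.frame(participant_id = "A",
                   phase = c("BASELINE", "TSST_P", "TSST_S", "TSST_A"),
                   minute_index = 0L, dhr = 1, deda = 1)
  lab <- label_blocks(fv)
  expect_equal(lab$phase, c("BASELINE", "TSST_S"))
  expect_equal(lab$label, c(0L, 1L))
  lab_a <- label_blocks(fv, include_tsst_a = TRUE)
  expect_equal(lab_a$phase, c("BASELINE", "TSST_S", "TSST_A"))
  expect_equal(lab_a$label, c(0L, 1L, 1L))
  expect_false("TSST_P" %in% lab_a$phase)
  expect_equal(nrow(label_blocks(fv[0, ])), 0)
})

test_that("split_dataset stratifies, honors the fraction, and is seeded", {
  s <- separable_samples(20)           # 20 per class
  sp <- split_dataset(s, 0.75, seed = 7)
  expect_equal(nrow(sp$train), 30)
  expect_equal(nrow(sp$test), 10)
  expect_equal(as.integer(table(sp$train$label)), c(15L, 15L))
  expect_equal(as.integer(table(sp$test$label)), c(5L, 5L))
  sp2 <- split_dataset(s, 0.75, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(s, 0.75, seed = 8)))
  all_in <- split_dataset(s, 1.0, seed = 7)
  expect_equal(nrow(all_in$train), 40)
  expect_equal(nrow(all_in$test), 0)
  expect_error(split_dataset(s[s$label == 1L, ], 0.75, 1), "both classes")
})

test_that("train_sgd separates well-separated clusters and is deterministic", {
  s <- separable_samples(50)
  m <- train_sgd(s, seed = 3)
  expect_equal(mean(predict(m, s)$label == s$label), 1.0)
  m2 <- train_sgd(s, seed = 3)
  expect_identical(m, m2)              # bit-for-bit within one build
  expect_false(identical(m$w_hr, train_sgd(s, seed = 4)$w_hr))
  # logistic loss option also separates
  ml <- train_sgd(s, seed = 3, loss = "log")
  expect_equal(mean(predict(ml, s)$label == s$label), 1.0)
  expect_error(train_sgd(s[s$label == 0L, ], 1), "single class")
  s0 <- s; s0$deda <- 2
  expect_error(train_sgd(s0, 1), "zero-variance")
})

test_that("predictions are scale-equivariant through standardization", {
  s <- separable_samples(50, seed = 12, spread = 0.4)
  m <- train_sgd(s, seed = 5)
  base <- predict(m, s)$label
  s_scaled <- s
  s_scaled$deda <- s$deda * 1000
  m_scaled <- train_sgd(s_scaled, seed = 5)
  expect_equal(predict(m_scaled, s_scaled)$label, base)
})

test_that("predict scores linearly and breaks score ties toward non-stress", {
  m <- structure(list(w_hr = 1, w_eda = 1, bias = 0,
                      center = c(0, 0), scale = c(1, 1),
                      hyperparams = list()), class = "stress_model")
  p <- predict(m, data.frame(dhr = c(1, -1, 0), deda = c(1, -1, 0)))
  expect_equal(p$score, c(2, -2, 0))
  expect_equal(p$label, c(1L, 0L, 0L))
  expect_error(predict(m, data.frame(dhr = NA_real_, deda = 1)),
               "non-finite")
})

test_that("adjust_bias shifts decisions monotonically with correct limits", {
  s <- separable_samples(30, spread = 0.8)
  m <- train_sgd(s, seed = 2)
  expect_identical(predict(adjust_bias(m, 0), s), predict(m, s))
  deltas <- seq(-5, 5, by = 0.25)
  rates <- vapply(deltas, function(d) {
    cm <- compute_metrics(count_outcomes(s$label,
                                         predict(adjust_bias(m, d), s)$label))
    c(cm$hit_rate, cm$false_alarm_rate)
  }, numeric(2))
  expect_true(all(diff(rates[1, ]) >= 0))
  expect_true(all(diff(rates[2, ]) >= 0))
  all_stress <- predict(adjust_bias(m, 1e9), s)$label
  expect_true(all(all_stress == 1L))
  expect_true(all(predict(adjust_bias(m, -1e9), s)$label == 0L))
})

test_that("cross_validate partitions exactly and nails separable data", {
  s <- separable_samples(25)
  cv <- cross_validate(s, n_folds = 5, seed = 13)
  expect_length(cv$fold_accuracies, 5)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_true(all(cv$fold_accuracies == 1))
  sizes <- table(cv$folds)
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_equal(sum(sizes), nrow(s))    # every sample in exactly one fold
  expect_error(cross_validate(s[1:3, ], n_folds = 5, 1), "fewer samples")
})

test_that("model JSON roundtrips", {
  m <- train_sgd(separable_samples(10), seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$w_hr, m$w_hr)
  expect_equal(back$center, m$center)
  expect_equal(back$hyperparams$loss, "hinge")
  s <- separable_samples(10)
  expect_equal(predict(back, s), predict(m, s))
})
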