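# Two-feature linear stress classifier trained by stochastic gradient
# descent on baseline-normalized mean heart rate (dhr, bpm) and mean skin
# conductance (deda, microsiemens). Training pairs baseline blocks
# (non-stress) against speech-task blocks (stress); arithmetic-task blocks
# can be added for held-out evaluation.

# Run code with a private, seeded RNG stream; the global stream is
# untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Label feature vectors for classifier training and evaluation
#'
#' Phase-derived ground truth: baseline blocks are non-stress (label 0),
#' speech-task (TSST-S) blocks are stress (label 1). Arithmetic-task
#' (TSST-A) blocks are also stress but are only included when
#' `include_tsst_a = TRUE` (held-out evaluation); anticipation (TSST-P)
#' blocks carry no stress assumption and are always excluded.
#'
#' @param features a `feature_vectors` data frame.
#' @param include_tsst_a include TSST-A rows with label 1 (default `FALSE`).
#' @return a `labeled_samples` data frame: `participant_id`, `phase`,
#'   `minute_index`, `dhr`, `deda`, `label`.
#' @export
label_blocks <- function(features, include_tsst_a = FALSE) {
  stopifnot(inherits(features, "data.frame"))
  keep_phases <- c("BASELINE", "TSST_S", if (include_tsst_a) "TSST_A")
  df <- features[features$phase %in% keep_phases, , drop = FALSE]
  df$label <- ifelse(df$phase == "BASELINE", 0L, 1L)
  rownames(df) <- NULL
  class(df) <- c("labeled_samples", "data.frame")
  df
}

#' Stratified train/test split of labeled minute blocks
#'
#' Blocks are split at minute-block level, stratified by label, with
#' `round(train_fraction * n)` of each class assigned to training (seeded,
#' deterministic).
#'
#' @param samples a `labeled_samples` data frame.
#' @param train_fraction fraction in (0, 1] assigned to training.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` data frames.
#' @export
split_dataset <- function(samples, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(samples, "data.frame"),
            train_fraction > 0, train_fraction <= 1)
  labs <- sort(unique(samples$label))
  if (!setequal(labs, c(0L, 1L))) {
    stop("split_dataset: both classes must be present", call. = FALSE)
  }
  if (train_fraction < 1 && any(table(samples$label) < 2L)) {
    stop("split_dataset: need >= 2 samples per class to split",
         call. = FALSE)
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(labs, function(l) {
      idx <- which(samples$label == l)
      idx <- sample(idx)
      n_tr <- round(train_fraction * length(idx))
      idx[seq_len(n_tr)]
    }))
  })
  idx_train <- sort(idx_train)
  train <- samples[idx_train, , drop = FALSE]
  test <- samples[setdiff(seq_len(nrow(samples)), idx_train), , drop = FALSE]
  rownames(train) <- NULL
  rownames(test) <- NULL
  list(train = train, test = test)
}

.feature_matrix <- function(samples) {
  x <- cbind(dhr = as.numeric(samples$dhr), deda = as.numeric(samples$deda))
  if (!all(is.finite(x))) {
    stop("non-finite feature values", call. = FALSE)
  }
  x
}

#' Train the linear stress model by stochastic gradient descent
#'
#' Features are standardized (center = training mean, scale = training
#' standard deviation, stored in the model), then a linear decision function
#' `s(x) = w_hr * x1 + w_eda * x2 + bias` is fitted by per-sample SGD on a
#' regularized hinge (default) or logistic loss. The learning rate follows
#' the `1 / (l2 * (t0 + t))` schedule with `t0` chosen so the initial step
#' matches the typical weight scale; data are reshuffled each epoch from the
#' given seed, so training is fully deterministic.
#'
#' @param train a `labeled_samples` data frame containing both classes.
#' @param seed integer RNG seed for the per-epoch shuffles.
#' @param epochs passes over the data (default 1000).
#' @param l2 L2 regularization strength (default 1e-4); the bias is not
#'   regularized.
#' @param loss `"hinge"` (default) or `"log"`.
#' @return an object of class `stress_model`: `w_hr`, `w_eda`, `bias`,
#'   `center`, `scale` (length-2, order dhr/deda), `hyperparams`.
#' @export
train_sgd <- function(train, seed = 1L, epochs = 1000L, l2 = 1e-4,
                      loss = c("hinge", "log")) {
  loss <- match.arg(loss)
  x <- .feature_matrix(train)
  y <- as.integer(train$label)
  if (length(unique(y)) < 2L) {
    stop("train_sgd: training data contain a single class", call. = FALSE)
  }
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  if (any(scale <= 0 | !is.finite(scale))) {
    stop("train_sgd: zero-variance feature; cannot standardize",
         call. = FALSE)
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(xs)

  # learning-rate schedule eta_t = 1 / (l2 * (t0 + t)); t0 set so the first
  # step is on the order of the typical weight norm 1/sqrt(sqrt(l2))
  typw <- sqrt(1 / sqrt(l2))
  t0 <- 1 / (typw * l2)

  w <- c(0, 0)
  b <- 0
  t <- 0
  x1 <- xs[, 1L]; x2 <- xs[, 2L]
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        t <- t + 1
        eta <- 1 / (l2 * (t0 + t))
        yi <- ys[i]
        s <- w[1L] * x1[i] + w[2L] * x2[i] + b
        w <- w * (1 - eta * l2)
        if (loss == "hinge") {
          if (yi * s < 1) {
            w[1L] <- w[1L] + eta * yi * x1[i]
            w[2L] <- w[2L] + eta * yi * x2[i]
            b <- b + eta * yi
          }
        } else {
          g <- yi / (1 + exp(yi * s))
          w[1L] <- w[1L] + eta * g * x1[i]
          w[2L] <- w[2L] + eta * g * x2[i]
          b <- b + eta * g
        }
      }
    }
  })
  structure(list(w_hr = w[1L], w_eda = w[2L], bias = b,
                 center = unname(center), scale = unname(scale),
                 hyperparams = list(loss = loss, l2 = l2,
                                    epochs = as.integer(epochs),
                                    seed = as.integer(seed))),
            class = "stress_model")
}

#' @export
print.stress_model <- function(x, ...) {
  cat(sprintf(
    "<stress_model: score = %.4f*dhr' + %.4f*deda' + %.4f (%s loss)>\n",
    x$w_hr, x$w_eda, x$bias, x$hyperparams$loss))
  invisible(x)
}

#' Classify feature vectors with a trained model
#'
#' Features are standardized with the model's stored scaler and scored by
#' the linear decision function. Label 1 (stress) when the score is strictly
#' positive; a score of exactly 0 ties toward non-stress.
#'
#' @param object a `stress_model`.
#' @param features a data frame with `dhr` and `deda` columns (or a 2-column
#'   matrix in that order).
#' @param ... unused.
#' @return a data frame with columns `score` and `label`.
#' @export
predict.stress_model <- function(object, features, ...) {
  if (is.matrix(features)) {
    features <- data.frame(dhr = features[, 1L], deda = features[, 2L])
  }
  x <- .feature_matrix(features)
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  score <- xs[, 1L] * object$w_hr + xs[, 2L] * object$w_eda + object$bias
  data.frame(score = score, label = as.integer(score > 0))
}

#' Shift the model's decision threshold via the bias term
#'
#' Adding `delta` to the bias moves the decision boundary: positive shifts
#' classify more blocks as stress (hit rate and false-alarm rate both rise),
#' negative shifts are more conservative. Weights and scaler are unchanged.
#'
#' @param model a `stress_model`.
#' @param delta amount added to the bias.
#' @return a new `stress_model`.
#' @export
adjust_bias <- function(model, delta) {
  stopifnot(inherits(model, "stress_model"), is.finite(delta))
  model$bias <- model$bias + delta
  model
}

#' Five-fold cross-validation of the SGD classifier
#'
#' Samples are shuffled (seeded) and dealt into `n_folds` near-equal folds
#' at minute-block level; each fold is held out once while the model is
#' trained on the remainder; fold accuracy is the fraction of held-out
#' blocks classified correctly.
#'
#' @param samples a `labeled_samples` data frame.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed for fold assignment and training.
#' @param ... passed to [train_sgd()] (`epochs`, `l2`, `loss`).
#' @return a `cv_result` list: `fold_accuracies`, `mean_accuracy`.
#' @export
cross_validate <- function(samples, n_folds = 5L, seed = 1L, ...) {
  stopifnot(inherits(samples, "data.frame"), n_folds >= 2L)
  n <- nrow(samples)
  if (n < n_folds) {
    stop("cross_validate: fewer samples than folds", call. = FALSE)
  }
  fold <- with_seed(seed, {
    f <- integer(n)
    f[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    f
  })
  acc <- vapply(seq_len(n_folds), function(k) {
    tr <- samples[fold != k, , drop = FALSE]
    te <- samples[fold == k, , drop = FALSE]
    if (length(unique(tr$label)) < 2L) {
      stop(sprintf(
        "cross_validate: training complement of fold %d lacks a class", k),
        call. = FALSE)
    }
    model <- train_sgd(tr, seed = seed, ...)
    mean(predict(model, te)$label == te$label)
  }, numeric(1))
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 folds = fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: folds %s, mean %.3f>\n",
              paste(sprintf("%.3f", x$fold_accuracies), collapse = " "),
              x$mean_accuracy))
  invisible(x)
}

#' Serialize / load a stress model as JSON
#'
#' @param model a `stress_model`.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "stress_model"))
  obj <- list(format = "stresstrace-model", version = 1L,
              w_hr = model$w_hr, w_eda = model$w_eda, bias = model$bias,
              center = model$center, scale = model$scale,
              hyperparams = model$hyperparams)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "stresstrace-model")) {
    stop(sprintf("read_model_json: %s is not a stress model file", path),
         call. = FALSE)
  }
  structure(list(w_hr = obj$w_hr, w_eda = obj$w_eda, bias = obj$bias,
                 center = obj$center, scale = obj$scale,
                 hyperparams = obj$hyperparams),
            class = "stress_model")
}
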