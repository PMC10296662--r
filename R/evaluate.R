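# Evaluation protocol: confusion matrices, macro metrics, stratified
# k-fold cross-validation, window-duration sweep and feature-method
# comparison.

#' End-to-end pipeline configuration
#'
#' Bundles the preprocessing, feature and model settings that one
#' classification decision depends on.
#'
#' @param window_ms Envelope block length, milliseconds.
#' @param feature_method `"rms"` or `"statistical"`.
#' @param subwindow_ms RMS-feature subwindow, milliseconds.
#' @param hidden Hidden-layer widths of the MLP.
#' @param dropout_rate Dropout ratio.
#' @param training A [training_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_ms = 50, feature_method = "rms",
                            subwindow_ms = 500, hidden = c(32L, 16L),
                            dropout_rate = 0.2,
                            training = training_config()) {
  structure(list(window_ms = window_ms, feature_method = feature_method,
                 subwindow_ms = subwindow_ms, hidden = hidden,
                 dropout_rate = dropout_rate, training = training),
            class = "pipeline_config")
}

#' Confusion matrix and classification metrics
#'
#' Builds the class x class confusion matrix (rows = true, columns =
#' predicted) and computes accuracy plus macro-averaged precision and
#' recall: per-class one-vs-rest values averaged with equal class weight.
#' A class never predicted contributes precision 0; a class absent from
#' the truth contributes recall 0.
#'
#' @param truth,predicted Equal-length vectors of class ids.
#' @param classes Class set; defaults to the union observed.
#' @return List: `confusion`, `accuracy`, `precision`, `recall`,
#'   `per_class` data.frame.
#' @export
confusion_and_metrics <- function(truth, predicted, classes = NULL) {
  assert_that(length(truth) == length(predicted),
              "`truth` and `predicted` must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  assert_that(all(c(truth, predicted) %in% classes),
              "label outside the class set")
  f <- function(x) factor(x, levels = classes)
  cm <- table(truth = f(truth), predicted = f(predicted))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  list(confusion = cm,
       accuracy = sum(tp) / sum(cm),
       precision = mean(prec),
       recall = mean(rec),
       per_class = data.frame(class = classes,
                              precision = as.numeric(prec),
                              recall = as.numeric(rec)))
}

# Stratified fold assignment: per class, shuffle then deal round-robin,
# so fold sizes are balanced within +/- 1 per class. k = n degenerates to
# leave-one-out.
fold_assignment <- function(y, k, seed) {
  if (k == length(y)) return(seq_along(y))
  assert_that(all(table(y) >= k), "every class needs at least k samples")
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Train on the non-test folds and predict the test fold; used by all CV
# entry points. Fold models get fresh seeded weights (base seed + fold).
cv_fold_predict <- function(dataset, folds, fold, config, seed) {
  te <- which(folds == fold)
  tr <- which(folds != fold)
  cfg <- config$training
  cfg$split <- c(train = 1)             # all non-test windows train
  cfg$seed <- derive_seed(seed, fold)
  model <- build_mlp(ncol(dataset$X), classes = dataset$levels,
                     hidden = config$hidden,
                     dropout_rate = config$dropout_rate,
                     output = if (length(dataset$levels) == 2) "sigmoid"
                              else "softmax",
                     seed = derive_seed(seed, 100 + fold))
  fit <- train_mlp(model, list(X = dataset$X[tr, , drop = FALSE],
                               y = dataset$y[tr]), cfg)
  P <- mlp_probabilities(fit$model, dataset$X[te, , drop = FALSE])
  list(test = te,
       predicted = dataset$levels[max.col(P, ties.method = "first")],
       probabilities = P)
}

#' Stratified k-fold cross-validation
#'
#' Assigns windows to k stratified folds (seeded), trains a fresh model
#' per fold on the other k-1 folds and predicts the held-out fold, then
#' pools all test predictions for the headline metrics. Per-fold metrics
#' are reported alongside.
#'
#' @param windows List of labeled `emg_window` objects, or an
#'   `emg_dataset` of already-extracted features.
#' @param k Number of folds.
#' @param config A [pipeline_config()].
#' @param seed Integer seed (fold assignment and per-fold model seeds).
#' @param folds Optional externally fixed fold assignment.
#' @return An `evaluation_report`: `accuracy`, `precision`, `recall`,
#'   `loss` (mean cross-entropy of pooled test predictions), `confusion`,
#'   `per_class`, `per_fold`, `folds`, `config`.
#' @export
kfold_cv <- function(windows, k = 10, config = pipeline_config(),
                     seed = 1L, folds = NULL) {
  seed <- assert_seed(seed)
  dataset <- if (inherits(windows, "emg_dataset")) windows else
    feature_dataset(windows, method = config$feature_method,
                    window_ms = config$window_ms,
                    subwindow_ms = config$subwindow_ms)
  if (is.null(folds)) folds <- fold_assignment(dataset$y, k, seed)
  predicted <- integer(length(dataset$y))
  P <- matrix(NA_real_, length(dataset$y), length(dataset$levels))
  per_fold <- vector("list", k)
  for (fold in seq_len(k)) {
    res <- cv_fold_predict(dataset, folds, fold, config, seed)
    predicted[res$test] <- res$predicted
    P[res$test, ] <- res$probabilities
    m <- confusion_and_metrics(dataset$y[res$test], res$predicted,
                               classes = dataset$levels)
    per_fold[[fold]] <- data.frame(fold = fold, n_test = length(res$test),
                                   accuracy = m$accuracy,
                                   precision = m$precision,
                                   recall = m$recall)
  }
  pooled <- confusion_and_metrics(dataset$y, predicted,
                                  classes = dataset$levels)
  Y <- one_hot(dataset$y, dataset$levels)
  loss <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
  structure(list(accuracy = pooled$accuracy, precision = pooled$precision,
                 recall = pooled$recall, loss = loss,
                 confusion = pooled$confusion,
                 per_class = pooled$per_class,
                 per_fold = do.call(rbind, per_fold),
                 folds = folds, k = k, config = config, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy %.4f, precision %.4f, recall %.4f, loss %.4f\n",
              x$k, x$accuracy, x$precision, x$recall, x$loss))
  cat("confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Window-duration sweep
#'
#' Re-segments the session at each candidate window duration,
#' re-extracts features (the subwindow count scales with the duration)
#' and records the k-fold CV accuracy, reproducing the duration-vs-
#' accuracy trade-off analysis.
#'
#' @param recordings List of `emg_recording` sessions.
#' @param schedules Matching list of `event_schedule`s.
#' @param durations Candidate window durations in seconds.
#' @param config A [pipeline_config()].
#' @param k Folds.
#' @param seed Integer seed.
#' @return data.frame `duration`, `accuracy`, `precision`, `recall`,
#'   sorted by duration.
#' @export
window_sweep <- function(recordings, schedules, durations,
                         config = pipeline_config(), k = 10, seed = 1L) {
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  if (inherits(schedules, "event_schedule")) schedules <- list(schedules)
  assert_that(length(recordings) == length(schedules),
              "`recordings` and `schedules` must pair up")
  durations <- sort(unique(durations))
  rows <- lapply(durations, function(d) {
    windows <- unlist(lapply(seq_along(recordings), function(i) {
      segment_recording(recordings[[i]], schedules[[i]], d)
    }), recursive = FALSE)
    rep <- kfold_cv(windows, k = k, config = config, seed = seed)
    data.frame(duration = d, accuracy = rep$accuracy,
               precision = rep$precision, recall = rep$recall)
  })
  do.call(rbind, rows)
}

#' Compare feature-extraction methods on identical folds
#'
#' Runs k-fold CV once per feature method, reusing one seeded fold
#' assignment so the comparison differs only in the features.
#'
#' @param windows List of labeled `emg_window` objects.
#' @param methods Feature methods to compare.
#' @param config Base [pipeline_config()] (its `feature_method` is
#'   overridden per run).
#' @param k Folds.
#' @param seed Integer seed.
#' @return List: `table` (one metrics row per method) and `reports`
#'   (named `evaluation_report`s, all sharing `folds`).
#' @export
compare_feature_methods <- function(windows,
                                    methods = c("rms", "statistical"),
                                    config = pipeline_config(), k = 10,
                                    seed = 1L) {
  seed <- assert_seed(seed)
  labs <- vapply(windows, function(w) w$label, integer(1))
  folds <- fold_assignment(labs, k, seed)
  reports <- lapply(methods, function(m) {
    cfg <- config
    cfg$feature_method <- m
    kfold_cv(windows, k = k, config = cfg, seed = seed, folds = folds)
  })
  names(reports) <- methods
  tab <- do.call(rbind, lapply(methods, function(m) {
    r <- reports[[m]]
    data.frame(method = m, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, loss = r$loss)
  }))
  list(table = tab, reports = reports)
}
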