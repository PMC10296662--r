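# Metrics, cross-validation, window sweep and feature comparison.
# CV tests run with reduced epochs; the full regime is exercised in
# test-acceptance.R.

fast_config <- function(epochs = 40, seed = 1) {
  pipeline_config(training = training_config(epochs = epochs, seed = seed))
}

test_that("confusion_and_metrics evaluates the worked examples", {
  # perfect two-class predictions
  perfect <- confusion_and_metrics(rep(1:2, each = 5), rep(1:2, each = 5))
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$precision, 1.0)
  expect_equal(perfect$recall, 1.0)
  # confusion [[3,1],[2,4]]: truth 1 predicted (3x1, 1x2); truth 2 (2x1, 4x2)
  truth <- c(rep(1, 4), rep(2, 6))
  pred <- c(1, 1, 1, 2, 1, 1, 2, 2, 2, 2)
  m <- confusion_and_metrics(truth, pred)
  expect_equal(as.numeric(m$confusion), c(3, 2, 1, 4))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, mean(c(3 / 5, 4 / 5)))   # hand-computed macro
  expect_equal(m$recall, mean(c(3 / 4, 4 / 6)))
  # all predictions one class on a balanced 3-class set
  collapsed <- confusion_and_metrics(rep(1:3, each = 4), rep(1, 12),
                                     classes = 1:3)
  expect_equal(collapsed$accuracy, 1 / 3)
  expect_equal(collapsed$precision, (1 / 3 + 0 + 0) / 3)  # absent -> 0
  expect_error(confusion_and_metrics(c(1, 4), c(1, 1), classes = 1:3),
               "outside")
})

test_that("metrics match the counting oracle on random label sets", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      classes <- sort(sample(1:6, sample(2:4, 1)))
      n <- sample(10:40, 1)
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
    })
    got <- confusion_and_metrics(truth, pred, classes = classes)
    want <- oracle_metrics(truth, pred, classes)
    expect_equal(as.numeric(got$confusion), as.numeric(want$confusion))
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    # row sums equal per-class true counts; grand total equals n
    expect_equal(as.numeric(rowSums(got$confusion)),
                 as.numeric(table(factor(truth, levels = classes))))
    expect_equal(sum(got$confusion), n)
  }
})

test_that("fold assignment partitions with stratification within +/- 1", {
  y <- rep(1:3, times = c(20, 23, 25))
  folds <- emgrip:::fold_assignment(y, 10, seed = 4)
  expect_length(folds, length(y))
  expect_setequal(unique(folds), 1:10)
  for (cls in 1:3) {
    counts <- table(factor(folds[y == cls], levels = 1:10))
    expect_lte(diff(range(counts)), 1)
  }
  expect_identical(folds, emgrip:::fold_assignment(y, 10, seed = 4))
  expect_error(emgrip:::fold_assignment(rep(1:2, times = c(5, 20)), 10),
               "k samples")
})

test_that("kfold_cv pools stratified fold predictions", {
  wins <- session_windows(seed = 11, reps = 4, overlap = 0)
  rep1 <- kfold_cv(wins, k = 4, config = fast_config(seed = 11), seed = 11)
  # every fold tests |windows|/k windows exactly (balanced by design)
  expect_equal(rep1$per_fold$n_test, rep(3, 4))
  expect_equal(sum(rep1$confusion), 12)
  expect_equal(rep1$accuracy, sum(diag(rep1$confusion)) / 12)
  expect_true(all(rep1$per_fold$accuracy >= 0 & rep1$per_fold$accuracy <= 1))
  # same seed twice: identical fold assignment and metrics
  rep2 <- kfold_cv(wins, k = 4, config = fast_config(seed = 11), seed = 11)
  expect_identical(rep1$folds, rep2$folds)
  expect_identical(rep1$accuracy, rep2$accuracy)
  expect_identical(rep1$confusion, rep2$confusion)
})

test_that("leave-one-out is the k = n edge case", {
  data <- blob_dataset(n_per_class = 4, p = 3, seed = 6)
  rep <- kfold_cv(data, k = 8, config = fast_config(epochs = 10, seed = 6),
                  seed = 6)
  expect_equal(rep$per_fold$n_test, rep(1, 8))
})

test_that("window_sweep is consistent with a direct CV call and sorted", {
  protocol <- protocol_config(repetitions_per_task = 4)
  sched <- build_schedule(protocol, seed = 9)
  rec <- synthesize_recording(sched, protocol, generator_config(seed = 9))
  cfg <- fast_config(seed = 9)
  tab <- window_sweep(rec, sched, durations = 2, config = cfg, k = 4,
                      seed = 9)
  direct <- kfold_cv(segment_recording(rec, sched, 2), k = 4, config = cfg,
                     seed = 9)
  expect_equal(tab$accuracy, direct$accuracy)
  # durations come back sorted regardless of input order
  tab2 <- window_sweep(rec, sched, durations = c(2, 0.5), config = cfg,
                       k = 4, seed = 9)
  expect_equal(tab2$duration, c(0.5, 2))
})

test_that("longer windows do not lose accuracy on full-task bursts", {
  # trend check over seeds: 2 s windows carry more evidence than 0.5 s
  accs <- vapply(1:3, function(seed) {
    protocol <- protocol_config(repetitions_per_task = 6)
    sched <- build_schedule(protocol, seed = seed)
    rec <- synthesize_recording(sched, protocol,
                                generator_config(class2_overlap = 0,
                                                 seed = seed))
    tab <- window_sweep(rec, sched, durations = c(0.5, 2),
                        config = fast_config(epochs = 60, seed = seed),
                        k = 6, seed = seed)
    tab$accuracy[match(c(0.5, 2), tab$duration)]
  }, numeric(2))
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
})

test_that("compare_feature_methods reuses one fold assignment", {
  wins <- session_windows(seed = 13, reps = 4, overlap = 0)
  res <- compare_feature_methods(wins, config = fast_config(seed = 13),
                                 k = 4, seed = 13)
  expect_equal(res$table$method, c("rms", "statistical"))
  expect_identical(res$reports$rms$folds, res$reports$statistical$folds)
  # identical method twice gives identical metric columns
  same <- compare_feature_methods(wins, methods = c("rms", "rms"),
                                  config = fast_config(seed = 13), k = 4,
                                  seed = 13)
  expect_equal(same$table$accuracy[1], same$table$accuracy[2])
})
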