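# The five-layer MLP: construction, forward pass, training, search,
# serialization.

test_that("build_mlp assembles the five-layer architecture", {
  m <- build_mlp(12, classes = 1:3, seed = 1)
  expect_length(m$layers, 5)
  kinds <- vapply(m$layers, function(l) l$kind, character(1))
  expect_equal(kinds, c("dense", "dropout", "dense", "dropout", "dense"))
  expect_equal(dim(m$dense[[1]]$W), c(12, 32))
  expect_equal(dim(m$dense[[3]]$W), c(16, 3))
  expect_equal(m$output, "softmax")
  # binary variant: final width 1 with sigmoid
  b <- build_mlp(12, classes = c(1L, 3L), output = "sigmoid", seed = 1)
  expect_equal(dim(b$dense[[3]]$W), c(16, 1))
  expect_error(build_mlp(12, classes = 1:3, output = "sigmoid"), "two")
  # equal seeds give identical initial weights; different seeds differ
  expect_identical(build_mlp(12, seed = 9)$dense,
                   build_mlp(12, seed = 9)$dense)
  expect_false(identical(build_mlp(12, seed = 9)$dense,
                         build_mlp(12, seed = 10)$dense))
})

test_that("forward pass is a normalized softmax with first-tie argmax", {
  m <- build_mlp(4, classes = 1:3, seed = 1)
  # all-zero weights and biases -> uniform distribution
  for (li in 1:3) m$dense[[li]]$W[] <- 0
  pred <- predict_mlp(m, c(1, 2, 3, 4))
  expect_equal(unname(pred$probabilities), rep(1 / 3, 3))
  expect_equal(pred$class, 1L)          # exact tie -> lowest class id
  expect_equal(pred$confidence, 1 / 3)
  for (seed in 1:5) {
    m2 <- build_mlp(4, classes = 1:3, seed = seed)
    x <- withr::with_seed(seed, rnorm(4))
    p <- predict_mlp(m2, x)$probabilities
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
  expect_error(predict_mlp(m, c(1, 2)), "does not match")
})

test_that("forward pass matches a hand-computed two-layer model", {
  m <- build_mlp(2, classes = 1:2, hidden = c(2, 2), seed = 1)
  m$dense[[1]]$W <- matrix(c(1, 0, 0, 1), 2, 2)
  m$dense[[1]]$b <- c(0, 0)
  m$dense[[2]]$W <- matrix(c(1, -1, 2, 1), 2, 2)
  m$dense[[2]]$b <- c(0.5, -0.5)
  m$dense[[3]]$W <- matrix(c(1, 0, 0, 1), 2, 2)
  m$dense[[3]]$b <- c(0, 0)
  x <- c(1, 2)
  # by hand: h1 = relu(x) = (1, 2); h2 = relu((1*1 + 2*(-1) + 0.5,
  # 1*2 + 2*1 - 0.5)) = (0, 3.5); softmax((0, 3.5))
  want <- exp(c(0, 3.5)) / sum(exp(c(0, 3.5)))
  expect_equal(unname(predict_mlp(m, x)$probabilities), want,
               tolerance = 1e-9)
})

test_that("forward pass matches the plain-arithmetic oracle", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      p <- sample(2:6, 1)
      cls <- sort(sample(1:9, sample(2:4, 1)))
      x <- rnorm(p)
    })
    out <- if (length(cls) == 2 && seed %% 2) "sigmoid" else "softmax"
    m <- build_mlp(p, classes = cls, hidden = c(5L, 4L), output = out,
                   seed = seed)
    expect_equal(unname(predict_mlp(m, x)$probabilities),
                 oracle_forward(m, x), tolerance = 1e-9)
  }
})

test_that("training learns separable data and is reproducible", {
  data <- blob_dataset(n_per_class = 15, seed = 3)
  m <- build_mlp(ncol(data$X), classes = data$levels, output = "sigmoid",
                 seed = 3)
  cfg <- training_config(epochs = 60, seed = 3)
  fit <- train_mlp(m, data, cfg)
  expect_equal(nrow(fit$history), 60)   # history lengths = epochs
  expect_equal(utils::tail(fit$history$accuracy, 1), 1.0)
  fit2 <- train_mlp(m, data, cfg)
  expect_identical(fit$model$dense, fit2$model$dense)
  expect_identical(fit$history, fit2$history)
})

test_that("learning_rate = 0 leaves the weights unchanged", {
  data <- blob_dataset(n_per_class = 6, seed = 1)
  m <- build_mlp(ncol(data$X), classes = data$levels, seed = 1)
  fit <- train_mlp(m, data, training_config(learning_rate = 0, epochs = 3,
                                            seed = 1))
  expect_equal(fit$model$dense, m$dense, tolerance = 1e-12)
})

test_that("training requires every class in the train split", {
  data <- blob_dataset(n_per_class = 4, seed = 1)
  data$y[] <- 1L
  data$levels <- c(1L, 2L)
  m <- build_mlp(ncol(data$X), classes = 1:2, seed = 1)
  expect_error(train_mlp(m, data, training_config(epochs = 2, seed = 1)),
               "training sample")
})

test_that("training loss is non-increasing in the small-step regime", {
  data <- blob_dataset(n_per_class = 12, p = 3, gap = 2, seed = 5)
  m <- build_mlp(3, classes = data$levels, seed = 5)
  fit <- train_mlp(m, data, training_config(learning_rate = 1e-4,
                                            epochs = 80, seed = 5))
  increases <- diff(fit$history$loss) > 1e-9
  expect_lte(mean(increases), 0.05)     # <= 5% violating epochs allowed
})

test_that("random_search scans lr and epochs and reports trials", {
  data <- blob_dataset(n_per_class = 10, seed = 2)
  one <- random_search(data, epoch_grid = c(10L, 20L), n_draws = 1,
                       base_cfg = training_config(seed = 2), seed = 2)
  expect_equal(one$best_trial, 1L)      # single trial is the best
  expect_equal(nrow(one$trials), 1)
  res <- random_search(data, epoch_grid = c(10L, 20L), n_draws = 4,
                       base_cfg = training_config(seed = 2), seed = 7)
  expect_true(all(res$trials$lr >= 1e-4 & res$trials$lr <= 1e-2))
  expect_true(all(res$trials$epochs %in% c(10L, 20L)))
  expect_equal(res$best_config$epochs, res$trials$epochs[res$best_trial])
  # ties break by trial order: degenerate single-point data
  deg <- blob_dataset(n_per_class = 6, gap = 0, seed = 1)
  deg$X[] <- 0
  tie <- random_search(deg, epoch_grid = 2L, n_draws = 3,
                       base_cfg = training_config(seed = 1), seed = 1)
  accs <- tie$trials$val_accuracy
  expect_equal(tie$best_trial, which(accs == max(accs))[1])
})

test_that("search result dominates single default runs on separable data", {
  for (seed in 1:5) {
    data <- blob_dataset(n_per_class = 10, seed = seed)
    cfg <- training_config(epochs = 100, seed = seed)
    m <- build_mlp(ncol(data$X), classes = data$levels, seed = seed)
    single <- utils::tail(train_mlp(m, data, cfg)$history$val_accuracy, 1)
    res <- random_search(data, epoch_grid = c(50L, 100L), n_draws = 5,
                         base_cfg = cfg, seed = seed)
    expect_gte(max(res$trials$val_accuracy, na.rm = TRUE), single)
  }
})

test_that("models serialize to JSON and back without loss", {
  dir <- withr::local_tempdir()
  data <- blob_dataset(n_per_class = 8, seed = 4)
  m <- train_mlp(build_mlp(4, classes = data$levels, seed = 4), data,
                 training_config(epochs = 5, seed = 4))$model
  path <- file.path(dir, "model.json")
  write_mlp(m, path)
  back <- read_mlp(path)
  expect_equal(back$dense, m$dense, tolerance = 1e-12)
  expect_equal(back$classes, m$classes)
  x <- withr::with_seed(4, rnorm(4))
  expect_equal(predict_mlp(back, x), predict_mlp(m, x))
})
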