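# Five-layer multilayer perceptron: dense(h1) -> dropout -> dense(h2) ->
# dropout -> dense(output). Hidden units are rectified-linear; the output
# is softmax over the classes (multiclass, categorical cross-entropy) or
# a single sigmoid unit (binary, binary cross-entropy). Training is
# mini-batch gradient descent with Adam; dropout is active only during
# training (inverted scaling, so inference needs no rescaling).

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)             # shift for numerical stability
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Training configuration
#'
#' Defaults mirror the regime the pipeline was tuned with: Adam at
#' learning rate 0.001, 300 epochs, batch size 8, 20% dropout, and a
#' 60/20/20 train/validation/test split.
#'
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param dropout_rate Dropout ratio of the two intermediate layers.
#' @param split Named fractions `train`, `val`, `test`, summing to 1.
#' @param seed Integer seed (mandatory: drives init, splits, shuffling
#'   and dropout masks).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 300,
                            batch_size = 8, dropout_rate = 0.2,
                            split = c(train = 0.6, val = 0.2, test = 0.2),
                            seed = 1L) {
  assert_scalar_num(learning_rate, "learning_rate", nonneg = TRUE)
  assert_that(epochs >= 1, "`epochs` must be >= 1")
  assert_that(batch_size >= 1, "`batch_size` must be >= 1")
  assert_that(abs(sum(split) - 1) < 1e-9, "`split` fractions must sum to 1")
  seed <- assert_seed(seed)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, split = split, seed = seed),
            class = "training_config")
}

#' Build the five-layer MLP
#'
#' Architecture: dense(hidden\[1\]) - dropout - dense(hidden\[2\]) -
#' dropout - dense(output). With `output = "softmax"` the final layer has
#' one unit per class; with `output = "sigmoid"` a single unit encodes
#' the two-class case (the higher class id is the positive class).
#' Weights are initialized uniformly in +/- 1/sqrt(fan_in) from `seed`;
#' biases start at zero.
#'
#' @param n_inputs Feature-vector length.
#' @param classes Integer vector of class ids (sorted internally).
#' @param hidden Widths of the two hidden dense layers.
#' @param dropout_rate Dropout ratio of the intermediate layers.
#' @param output `"softmax"` or `"sigmoid"` (sigmoid requires exactly two
#'   classes).
#' @param seed Integer seed for weight initialization.
#' @return An `mlp_model`.
#' @export
build_mlp <- function(n_inputs, classes = c(1L, 2L, 3L),
                      hidden = c(32L, 16L), dropout_rate = 0.2,
                      output = c("softmax", "sigmoid"), seed = 1L) {
  output <- match.arg(output)
  assert_that(n_inputs >= 1, "`n_inputs` must be >= 1")
  assert_that(all(hidden >= 1) && length(hidden) == 2,
              "`hidden` must be two positive widths")
  assert_that(dropout_rate > 0 && dropout_rate < 1,
              "`dropout_rate` must lie in (0, 1)")
  classes <- sort(as.integer(unique(classes)))
  if (output == "sigmoid") {
    assert_that(length(classes) == 2,
                "sigmoid output requires exactly two classes")
  }
  n_out <- if (output == "sigmoid") 1L else length(classes)
  widths <- c(n_inputs, hidden[1], hidden[2], n_out)
  seed <- assert_seed(seed)
  dense <- withr::with_seed(seed, lapply(1:3, function(i) {
    lim <- 1 / sqrt(widths[i])
    list(W = matrix(stats::runif(widths[i] * widths[i + 1], -lim, lim),
                    widths[i], widths[i + 1]),
         b = rep(0, widths[i + 1]))
  }))
  layers <- list(
    list(kind = "dense", index = 1L, activation = "relu"),
    list(kind = "dropout", rate = dropout_rate),
    list(kind = "dense", index = 2L, activation = "relu"),
    list(kind = "dropout", rate = dropout_rate),
    list(kind = "dense", index = 3L, activation = output))
  structure(list(layers = layers, dense = dense, n_inputs = as.integer(n_inputs),
                 classes = classes, output = output, seed = seed),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  widths <- vapply(x$dense, function(d) ncol(d$W), integer(1))
  cat(sprintf("mlp_model: %d inputs -> dense(%d) -> dropout -> dense(%d) -> dropout -> dense(%d, %s); classes {%s}\n",
              x$n_inputs, widths[1], widths[2], widths[3], x$output,
              paste(x$classes, collapse = ",")))
  invisible(x)
}

# Forward pass over a batch (rows = samples). When training, dropout
# masks are sampled from the current RNG stream and activations cached
# for backpropagation.
mlp_forward_batch <- function(model, X, training = FALSE) {
  a <- X
  cache <- list(a0 = X)
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$kind == "dense") {
      d <- model$dense[[layer$index]]
      z <- a %*% d$W + matrix(d$b, nrow(a), length(d$b), byrow = TRUE)
      a <- switch(layer$activation,
                  relu = relu(z),
                  softmax = softmax_rows(z),
                  sigmoid = sigmoid(z))
      cache[[paste0("z", layer$index)]] <- z
      cache[[paste0("a", layer$index)]] <- a
    } else if (training) {
      keep <- matrix(stats::runif(length(a)) >= layer$rate,
                     nrow(a), ncol(a))
      a <- a * keep / (1 - layer$rate)
      cache[[paste0("a", model$layers[[li - 1]]$index)]] <- a
      cache[[paste0("mask", model$layers[[li - 1]]$index)]] <- keep
    }
  }
  cache$out <- a
  cache
}

# Class probabilities for a batch: softmax rows directly; a sigmoid unit
# expands to (1 - p, p) over the sorted class pair.
mlp_probabilities <- function(model, X) {
  out <- mlp_forward_batch(model, X, training = FALSE)$out
  if (model$output == "sigmoid") {
    p <- out[, 1]
    out <- cbind(1 - p, p)
  }
  colnames(out) <- as.character(model$classes)
  out
}

#' Classify one feature vector
#'
#' Deterministic inference pass (dropout inactive). The predicted class
#' is the argmax of the class probabilities, with the lowest class id
#' winning exact ties; `confidence` is the maximum probability and is
#' what the streaming gate thresholds.
#'
#' @param model An `mlp_model`.
#' @param features An `emg_features` vector or plain numeric vector of
#'   length `n_inputs`.
#' @return An `emg_prediction`: `class`, per-class `probabilities`
#'   (summing to 1), `confidence`.
#' @export
predict_mlp <- function(model, features) {
  stopifnot(inherits(model, "mlp_model"))
  x <- if (inherits(features, "emg_features")) features$values else
    as.numeric(features)
  assert_that(length(x) == model$n_inputs,
              sprintf("feature length %d does not match model inputs %d",
                      length(x), model$n_inputs))
  p <- mlp_probabilities(model, matrix(x, 1))[1, ]
  k <- which.max(p)                      # which.max takes the first tie
  structure(list(class = model$classes[k], probabilities = p,
                 confidence = unname(p[k])),
            class = "emg_prediction")
}

# One-hot encode labels against the model's sorted class levels.
one_hot <- function(y, classes) {
  idx <- match(y, classes)
  assert_that(!anyNA(idx), "label outside the model's class set")
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), idx)] <- 1
  Y
}

# Stratified index split by label into named fractions. Per class the
# counts are floor(fraction * n) with leftovers dealt to the largest
# fractional remainders, so every positive fraction receives samples
# whenever the class is large enough.
stratified_split <- function(y, split, seed) {
  parts <- lapply(names(split), function(nm) integer(0))
  names(parts) <- names(split)
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_each <- floor(split * n)
      short <- n - sum(n_each)
      if (short > 0) {
        extra <- order(split * n - n_each, decreasing = TRUE)[seq_len(short)]
        n_each[extra] <- n_each[extra] + 1
      }
      at <- 1
      for (j in seq_along(split)) {
        if (n_each[j] > 0) {
          parts[[j]] <- c(parts[[j]], idx[at:(at + n_each[j] - 1)])
          at <- at + n_each[j]
        }
      }
    }
  })
  parts
}

# Mean loss and accuracy of a model on (X, y); cross-entropy matching the
# output activation.
mlp_eval <- function(model, X, y, eps = 1e-12) {
  if (length(y) == 0) return(c(loss = NA_real_, accuracy = NA_real_))
  P <- mlp_probabilities(model, X)
  Y <- one_hot(y, model$classes)
  loss <- -mean(rowSums(Y * log(pmax(P, eps))))
  pred <- model$classes[max.col(P, ties.method = "first")]
  c(loss = loss, accuracy = mean(pred == y))
}

#' Train the MLP
#'
#' Mini-batch Adam on cross-entropy (categorical for softmax, binary for
#' the sigmoid unit). The dataset is split per `cfg$split` (stratified,
#' seeded); training runs on the train part with dropout active, and the
#' per-epoch history records loss and accuracy on the train and
#' validation parts with dropout inactive. Fully reproducible from
#' `cfg$seed`.
#'
#' @param model An `mlp_model` from [build_mlp()].
#' @param data An `emg_dataset` from [feature_dataset()], or a list with
#'   `X` and `y`.
#' @param cfg A [training_config()].
#' @return A `trained_mlp` list: the trained `model`, a `history`
#'   data.frame (epoch, loss, accuracy, val_loss, val_accuracy) and the
#'   `split` indices used.
#' @export
train_mlp <- function(model, data, cfg = training_config()) {
  stopifnot(inherits(model, "mlp_model"))
  X <- as.matrix(data$X); y <- as.integer(data$y)
  assert_that(ncol(X) == model$n_inputs,
              "feature width does not match the model's input width")
  split <- stratified_split(y, cfg$split, derive_seed(cfg$seed, 1))
  tr <- split$train %||% seq_along(y)
  va <- split$val %||% integer(0)
  assert_that(all(model$classes %in% y[tr]),
              "every class needs at least one training sample")
  state <- fit_state_init(model)
  hist <- matrix(NA_real_, cfg$epochs, 4,
                 dimnames = list(NULL, c("loss", "accuracy", "val_loss",
                                         "val_accuracy")))
  for (ep in seq_len(cfg$epochs)) {
    state <- withr::with_seed(derive_seed(cfg$seed, 1000 + ep), {
      fit_epoch(model, state, X[tr, , drop = FALSE], y[tr], cfg)
    })
    model$dense <- state$dense
    hist[ep, 1:2] <- mlp_eval(model, X[tr, , drop = FALSE], y[tr])
    hist[ep, 3:4] <- mlp_eval(model, X[va, , drop = FALSE], y[va])
    if (!is.finite(hist[ep, 1])) {
      stop(sprintf("training diverged: non-finite loss at epoch %d", ep),
           call. = FALSE)
    }
  }
  structure(list(model = model,
                 history = data.frame(epoch = seq_len(cfg$epochs), hist),
                 split = split),
            class = "trained_mlp")
}

fit_state_init <- function(model) {
  zeros <- lapply(model$dense, function(d)
    list(W = d$W * 0, b = d$b * 0))
  list(dense = model$dense, m = zeros, v = zeros, t = 0)
}

# One epoch of shuffled mini-batch Adam updates. Runs inside a seeded RNG
# scope (shuffle order and dropout masks draw from it).
fit_epoch <- function(model, state, X, y, cfg,
                      beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  ord <- sample(nrow(X))
  Y <- one_hot(y, model$classes)
  target_binary <- model$output == "sigmoid"
  starts <- seq(1, nrow(X), by = cfg$batch_size)
  for (s in starts) {
    idx <- ord[s:min(s + cfg$batch_size - 1, nrow(X))]
    Xb <- X[idx, , drop = FALSE]
    m <- nrow(Xb)
    model$dense <- state$dense
    cache <- mlp_forward_batch(model, Xb, training = TRUE)
    # output delta: (p - y)/m for softmax+CCE and sigmoid+BCE alike
    Tb <- if (target_binary) {
      matrix(Y[idx, 2], ncol = 1)
    } else {
      Y[idx, , drop = FALSE]
    }
    delta <- (cache$out - Tb) / m
    grads <- vector("list", 3)
    for (li in 3:1) {
      a_prev <- cache[[paste0("a", li - 1)]]
      grads[[li]] <- list(W = t(a_prev) %*% delta, b = colSums(delta))
      if (li > 1) {
        delta <- delta %*% t(state$dense[[li]]$W)
        mask <- cache[[paste0("mask", li - 1)]]
        rate <- model$layers[[2 * li - 2]]$rate
        delta <- delta * mask / (1 - rate)
        delta <- delta * (cache[[paste0("z", li - 1)]] > 0)
      }
    }
    state$t <- state$t + 1
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (li in 1:3) {
      for (par in c("W", "b")) {
        g <- grads[[li]][[par]]
        state$m[[li]][[par]] <- beta1 * state$m[[li]][[par]] + (1 - beta1) * g
        state$v[[li]][[par]] <- beta2 * state$v[[li]][[par]] +
          (1 - beta2) * g^2
        state$dense[[li]][[par]] <- state$dense[[li]][[par]] -
          cfg$learning_rate * (state$m[[li]][[par]] / bc1) /
          (sqrt(state$v[[li]][[par]] / bc2) + adam_eps)
      }
    }
  }
  state
}

#' Random hyperparameter search
#'
#' Draws `n_draws` configurations — learning rate log-uniform in
#' `lr_range`, epochs uniform over `epoch_grid`, batch size constant —
#' trains each on the train split and scores it on the validation split.
#' Returns the configuration with the highest validation accuracy
#' (first-seen tie-break) plus the full trial table; a failed trial is
#' recorded, not fatal.
#'
#' @param data An `emg_dataset`.
#' @param lr_range Two-element learning-rate range.
#' @param epoch_grid Candidate epoch counts.
#' @param n_draws Number of random draws.
#' @param base_cfg [training_config()] supplying the constant fields.
#' @param hidden,dropout_rate Architecture of each trial model.
#' @param seed Integer seed for the draws.
#' @return List: `best_config` (a `training_config`), `best_trial` row
#'   index, `trials` data.frame (lr, epochs, val_accuracy, error).
#' @export
random_search <- function(data, lr_range = c(1e-4, 1e-2),
                          epoch_grid = c(100L, 200L, 300L), n_draws = 5,
                          base_cfg = training_config(),
                          hidden = c(32L, 16L), dropout_rate = 0.2,
                          seed = 1L) {
  assert_that(n_draws >= 1, "`n_draws` must be >= 1")
  seed <- assert_seed(seed)
  draws <- withr::with_seed(seed, data.frame(
    lr = exp(stats::runif(n_draws, log(lr_range[1]), log(lr_range[2]))),
    epochs = as.integer(epoch_grid)[sample.int(length(epoch_grid), n_draws,
                                               replace = TRUE)]))
  draws$val_accuracy <- NA_real_
  draws$error <- NA_character_
  for (i in seq_len(n_draws)) {
    cfg <- base_cfg
    cfg$learning_rate <- draws$lr[i]
    cfg$epochs <- draws$epochs[i]
    res <- tryCatch({
      model <- build_mlp(ncol(data$X), classes = data$levels,
                         hidden = hidden, dropout_rate = dropout_rate,
                         seed = derive_seed(seed, i))
      fit <- train_mlp(model, data, cfg)
      utils::tail(fit$history$val_accuracy, 1)
    }, error = function(e) conditionMessage(e))
    if (is.numeric(res) && is.finite(res)) draws$val_accuracy[i] <- res
    else if (is.character(res)) draws$error[i] <- res
    else draws$error[i] <- "empty validation split"
  }
  ok <- which(!is.na(draws$val_accuracy))
  assert_that(length(ok) > 0, "every search trial failed")
  best <- ok[which.max(draws$val_accuracy[ok])]
  best_cfg <- base_cfg
  best_cfg$learning_rate <- draws$lr[best]
  best_cfg$epochs <- draws$epochs[best]
  list(best_config = best_cfg, best_trial = best, trials = draws)
}

#' Serialize / restore a model
#'
#' The portable on-disk form is JSON: architecture fields plus flat
#' weight arrays per dense layer.
#'
#' @param model An `mlp_model`.
#' @param path Output / input file path.
#' @return `write_mlp`: the path, invisibly. `read_mlp`: the model.
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(n_inputs = model$n_inputs, classes = model$classes,
              output = model$output, seed = model$seed,
              dropout_rate = model$layers[[2]]$rate,
              hidden = vapply(model$dense[1:2], function(d) ncol(d$W),
                              integer(1)),
              dense = lapply(model$dense, function(d)
                list(dim = dim(d$W), W = as.numeric(d$W),
                     b = as.numeric(d$b))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- build_mlp(obj$n_inputs, classes = obj$classes,
                     hidden = obj$hidden, dropout_rate = obj$dropout_rate,
                     output = obj$output, seed = obj$seed)
  for (li in 1:3) {
    d <- if (is.data.frame(obj$dense)) obj$dense[li, ] else obj$dense[[li]]
    model$dense[[li]]$W <- matrix(unlist(d$W), unlist(d$dim)[1],
                                  unlist(d$dim)[2])
    model$dense[[li]]$b <- as.numeric(unlist(d$b))
  }
  model
}
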