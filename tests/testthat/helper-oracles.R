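# Independent brute-force oracles (explicit loops, no shared code with
# the implementation) and small fixture builders.

# RMS envelope by explicit per-block loops.
oracle_rms_envelope <- function(x, n_block) {
  x <- as.matrix(x)
  k <- floor(nrow(x) / n_block)
  out <- matrix(0, k, ncol(x))
  for (ch in seq_len(ncol(x))) {
    for (b in seq_len(k)) {
      s <- 0
      for (i in ((b - 1) * n_block + 1):(b * n_block)) s <- s + x[i, ch]^2
      out[b, ch] <- sqrt(s / n_block)
    }
  }
  out
}

# Peak normalization by explicit loops; zero-peak channels stay zero.
oracle_peak_normalize <- function(v) {
  out <- v
  for (ch in seq_len(ncol(v))) {
    pk <- v[1, ch]
    for (i in seq_len(nrow(v))) if (v[i, ch] > pk) pk <- v[i, ch]
    for (i in seq_len(nrow(v))) {
      out[i, ch] <- if (pk > 0) v[i, ch] / pk else 0
    }
  }
  out
}

# Subwindow RMS features, channel-major then time.
oracle_rms_features <- function(v, n_sub) {
  k <- floor(nrow(v) / n_sub)
  out <- numeric(0)
  for (ch in seq_len(ncol(v))) {
    for (b in seq_len(k)) {
      s <- 0
      for (i in ((b - 1) * n_sub + 1):(b * n_sub)) s <- s + v[i, ch]^2
      out <- c(out, sqrt(s / n_sub))
    }
  }
  out
}

# The six amplitude statistics, from their definitions: MAV, the two
# weighted MAVs (flat 0.5 tails; symmetric 4n/N and 4(N-n)/N ramps),
# median absolute value via sorting, population variance and sd.
oracle_stat_features <- function(v) {
  n <- nrow(v)
  out <- numeric(0)
  for (ch in seq_len(ncol(v))) {
    a <- abs(v[, ch])
    mav <- sum(a) / n
    w1 <- w2 <- numeric(n)
    for (i in seq_len(n)) {
      central <- (i >= 0.25 * n) && (i <= 0.75 * n)
      w1[i] <- if (central) 1 else 0.5
      w2[i] <- if (central) 1 else if (i < 0.25 * n) 4 * i / n
               else 4 * (n - i) / n
    }
    srt <- sort(a)
    med <- if (n %% 2 == 1) srt[(n + 1) / 2] else
      (srt[n / 2] + srt[n / 2 + 1]) / 2
    mu <- sum(v[, ch]) / n
    va <- sum((v[, ch] - mu)^2) / n
    out <- c(out, mav, sum(w1 * a) / n, sum(w2 * a) / n, med, va, sqrt(va))
  }
  out
}

# Forward pass by plain scalar arithmetic (dropout inactive).
oracle_forward <- function(model, x) {
  a <- as.numeric(x)
  for (li in 1:2) {
    d <- model$dense[[li]]
    z <- numeric(length(d$b))
    for (j in seq_along(d$b)) {
      s <- d$b[j]
      for (i in seq_along(a)) s <- s + a[i] * d$W[i, j]
      z[j] <- if (s > 0) s else 0
    }
    a <- z
  }
  d <- model$dense[[3]]
  z <- numeric(length(d$b))
  for (j in seq_along(d$b)) {
    s <- d$b[j]
    for (i in seq_along(a)) s <- s + a[i] * d$W[i, j]
    z[j] <- s
  }
  if (model$output == "softmax") {
    e <- exp(z - max(z))
    e / sum(e)
  } else {
    p <- 1 / (1 + exp(-z))
    c(1 - p, p)
  }
}

# Confusion counts and macro metrics by explicit counting.
oracle_metrics <- function(truth, predicted, classes) {
  k <- length(classes)
  cm <- matrix(0, k, k)
  for (i in seq_along(truth)) {
    cm[match(truth[i], classes), match(predicted[i], classes)] <-
      cm[match(truth[i], classes), match(predicted[i], classes)] + 1
  }
  prec <- rec <- numeric(k)
  for (j in seq_len(k)) {
    prec[j] <- if (sum(cm[, j]) > 0) cm[j, j] / sum(cm[, j]) else 0
    rec[j] <- if (sum(cm[j, ]) > 0) cm[j, j] / sum(cm[j, ]) else 0
  }
  list(confusion = cm, accuracy = sum(diag(cm)) / length(truth),
       precision = mean(prec), recall = mean(rec))
}

# -- fixture builders ------------------------------------------------------

# Short protocol for fast synthgen tests.
small_protocol <- function(...) {
  protocol_config(task_duration = 1, rest_duration = 0.5,
                  repetitions_per_task = 2, ...)
}

# A random unstructured recording for I/O round-trips.
random_recording <- function(seed, n = 50, n_emg = 3, n_imu = 6,
                             label = NULL) {
  withr::with_seed(seed, recording(
    emg = matrix(rnorm(n * n_emg), n, n_emg),
    imu = matrix(rnorm(n * n_imu), n, n_imu),
    sampling_rate = 1000, label = label,
    trial_id = sprintf("t%02d", seed %% 100)))
}

# A normalized-envelope object wrapping given values (for direct feature
# tests).
as_nenv <- function(values, envelope_rate = 20, label = NULL) {
  values <- as.matrix(values)
  structure(list(values = values,
                 peak_per_channel = apply(values, 2, max),
                 envelope_rate = envelope_rate, source_window_ms = 50,
                 label = label),
            class = "emg_nenv")
}

as_envelope <- function(values, envelope_rate = 20) {
  structure(list(values = as.matrix(values), envelope_rate = envelope_rate,
                 source_window_ms = 50, label = NULL),
            class = "emg_envelope")
}

# Two linearly separable Gaussian blobs as a feature dataset.
blob_dataset <- function(n_per_class = 20, p = 4, gap = 4, seed = 1,
                         classes = c(1L, 2L)) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_along(classes), function(k) {
      matrix(rnorm(n_per_class * p, mean = (k - 1) * gap), n_per_class, p)
    }))
    y <- rep(classes, each = n_per_class)
    ord <- sample(length(y))
    structure(list(X = X[ord, , drop = FALSE], y = y[ord],
                   levels = sort(classes)), class = "emg_dataset")
  })
}

# Labeled EMG windows from a seeded synthetic session.
session_windows <- function(seed, reps = 10, overlap = 0.5,
                            window_duration = 2) {
  protocol <- protocol_config(repetitions_per_task = reps)
  sched <- build_schedule(protocol, seed = seed)
  gen <- generator_config(class2_overlap = overlap, seed = seed)
  rec <- synthesize_recording(sched, protocol, gen)
  segment_recording(rec, sched, window_duration)
}

# Hand-built alternating flexion/extension schedule (2 s events, no
# rest) for streaming tests.
alternating_schedule <- function(n_pairs = 10, event_s = 2) {
  cls <- rep(c(1L, 3L), n_pairs)
  sched <- data.frame(class = cls,
                      onset = (seq_along(cls) - 1) * event_s,
                      offset = seq_along(cls) * event_s)
  class(sched) <- c("event_schedule", "data.frame")
  sched
}
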