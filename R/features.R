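# Time-domain feature extraction from the normalized envelope.
#
# Two candidate feature sets are supported, both computed per channel on
# the peak-normalized envelope and concatenated channel-major:
#  * rms          — RMS over consecutive non-overlapping subwindows
#                   (500 ms by default: 4 values per channel on a 2 s
#                   window), preserving the temporal course of activation;
#  * statistical  — six classical amplitude statistics: mean absolute
#                   value (MAV), its two weighted variants MAV1/MAV2,
#                   median absolute value, variance and standard
#                   deviation.
#
# MAV1 weights samples 1 inside the central 25-75% of the window and 0.5
# outside. MAV2 replaces the flat 0.5 tails by continuous ramps: 4n/N
# rising before the central band and 4(N-n)/N falling after it, so both
# variants de-emphasize window edges while MAV2 does so smoothly.

feature_vector <- function(values, method, n_channels, per_channel,
                           label = NULL) {
  assert_that(all(is.finite(values)), "features must all be finite")
  structure(list(values = as.numeric(values),
                 layout = list(method = method, n_channels = n_channels,
                               per_channel = per_channel),
                 label = if (is.null(label)) NULL else as.integer(label)),
            class = "emg_features")
}

#' Subwindow-RMS features
#'
#' Cuts each channel's normalized envelope into consecutive
#' non-overlapping subwindows of `subwindow_ms` and reduces each to its
#' RMS; a trailing remainder shorter than one subwindow is dropped.
#' Features are ordered channel-major, then time. On the default 2 s
#' window with a 50 ms envelope this yields 4 features per channel.
#'
#' @param nenv An `emg_nenv` from [peak_normalize()].
#' @param subwindow_ms Subwindow length in milliseconds.
#' @return An `emg_features` vector with the `rms` layout.
#' @export
rms_features <- function(nenv, subwindow_ms = 500) {
  stopifnot(inherits(nenv, "emg_nenv"))
  n_sub <- round(subwindow_ms / 1000 * nenv$envelope_rate)
  assert_that(n_sub >= 1, "`subwindow_ms` converts to < 1 envelope sample")
  n_env <- nrow(nenv$values)
  assert_that(n_sub <= n_env,
              "`subwindow_ms` is longer than the analysis window")
  k <- floor(n_env / n_sub)
  vals <- c(apply(nenv$values, 2, function(ch) {
    vapply(seq_len(k), function(j) {
      sqrt(mean(ch[((j - 1) * n_sub + 1):(j * n_sub)]^2))
    }, numeric(1))
  }))
  feature_vector(vals, "rms", ncol(nenv$values), k, nenv$label)
}

# Weight profiles for the MAV variants over an N-sample window (1-based
# sample index n).
mav1_weights <- function(n_samples) {
  n <- seq_len(n_samples)
  w <- rep(0.5, n_samples)
  w[n >= 0.25 * n_samples & n <= 0.75 * n_samples] <- 1
  w
}

mav2_weights <- function(n_samples) {
  n <- seq_len(n_samples)
  w <- rep(1, n_samples)
  lo <- n < 0.25 * n_samples
  hi <- n > 0.75 * n_samples
  w[lo] <- 4 * n[lo] / n_samples
  w[hi] <- 4 * (n_samples - n[hi]) / n_samples
  w
}

#' Statistical features
#'
#' Per channel, six amplitude statistics of the normalized envelope, in
#' the order MAV, MAV1, MAV2, median absolute value, variance, standard
#' deviation (channel-major concatenation). Variance and standard
#' deviation use the population denominator N, consistent with the
#' envelope's 1/N convention.
#'
#' @param nenv An `emg_nenv` from [peak_normalize()].
#' @return An `emg_features` vector with the `statistical` layout
#'   (6 features per channel).
#' @export
statistical_features <- function(nenv) {
  stopifnot(inherits(nenv, "emg_nenv"))
  n <- nrow(nenv$values)
  assert_that(n >= 1, "envelope is empty")
  w1 <- mav1_weights(n)
  w2 <- mav2_weights(n)
  vals <- c(apply(nenv$values, 2, function(ch) {
    a <- abs(ch)
    v <- mean(ch^2) - mean(ch)^2          # population variance
    c(mav = mean(a),
      mav1 = mean(w1 * a),
      mav2 = mean(w2 * a),
      medav = stats::median(a),
      var = v,
      sd = sqrt(max(v, 0)))
  }))
  feature_vector(vals, "statistical", ncol(nenv$values), 6L, nenv$label)
}

#' Full feature-extraction chain for one analysis window
#'
#' Composition of the pipeline stages: RMS envelope smoothing, then
#' peak-dynamic normalization, then one of the two feature extractors.
#' The window's label propagates to the feature vector.
#'
#' @param win An `emg_window`.
#' @param method `"rms"` or `"statistical"`.
#' @param window_ms Envelope block length, milliseconds.
#' @param subwindow_ms RMS-feature subwindow, milliseconds.
#' @return An `emg_features` vector.
#' @export
extract_features <- function(win, method = c("rms", "statistical"),
                             window_ms = 50, subwindow_ms = 500) {
  method <- match.arg(method)
  nenv <- peak_normalize(rms_envelope(win, window_ms = window_ms))
  switch(method,
         rms = rms_features(nenv, subwindow_ms = subwindow_ms),
         statistical = statistical_features(nenv))
}

#' Assemble a labeled feature dataset
#'
#' Stacks feature vectors extracted from a list of labeled windows into
#' the matrix form consumed by the classifier.
#'
#' @param windows List of labeled `emg_window` objects.
#' @param method,window_ms,subwindow_ms Passed to [extract_features()].
#' @return An `emg_dataset`: feature matrix `X` (n x p), integer labels
#'   `y`, sorted class `levels`.
#' @export
feature_dataset <- function(windows, method = "rms", window_ms = 50,
                            subwindow_ms = 500) {
  feats <- lapply(windows, extract_features, method = method,
                  window_ms = window_ms, subwindow_ms = subwindow_ms)
  labs <- vapply(feats, function(f) {
    assert_that(!is.null(f$label), "all windows must be labeled")
    f$label
  }, integer(1))
  X <- do.call(rbind, lapply(feats, function(f) f$values))
  structure(list(X = X, y = labs, levels = sort(unique(labs))),
            class = "emg_dataset")
}
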