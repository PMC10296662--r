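# Signal conditioning: Nyquist sizing, RMS envelope, peak normalization.

#' Minimum sampling rate for a band-limited signal
#'
#' Nyquist's criterion: a signal whose highest frequency component is
#' `fmax` must be sampled at 2 * fmax or faster to be reconstructable.
#'
#' @param fmax Highest signal frequency, Hz.
#' @return The minimum sampling rate in Hz.
#' @export
nyquist_min_rate <- function(fmax) {
  assert_scalar_num(fmax, "fmax", positive = TRUE)
  2 * fmax
}

#' RMS envelope of an analysis window
#'
#' Smooths each channel by mapping consecutive non-overlapping blocks of
#' `window_ms` milliseconds to their root-mean-square,
#' sqrt(sum(x_n^2) / N) over the N samples of each block. A trailing
#' remainder shorter than one block is dropped. 50 ms is the block size
#' that best preserves the activation shape at 1 kHz while suppressing
#' sample-level noise.
#'
#' @param win An `emg_window` (or plain samples x channels matrix plus
#'   `sampling_rate`).
#' @param window_ms Block length in milliseconds.
#' @param hop_ms Hop between block starts; defaults to the block length
#'   (non-overlapping blocks).
#' @param sampling_rate Required when `win` is a bare matrix.
#' @return An `emg_envelope`: non-negative `values` matrix
#'   (blocks x channels), `envelope_rate` in Hz, `source_window_ms`.
#' @export
rms_envelope <- function(win, window_ms = 50, hop_ms = window_ms,
                         sampling_rate = NULL) {
  if (inherits(win, "emg_window")) {
    x <- win$samples
    fs <- win$sampling_rate
    label <- win$label
  } else {
    x <- as.matrix(win)
    assert_that(!is.null(sampling_rate),
                "`sampling_rate` is required for matrix input")
    fs <- sampling_rate
    label <- NULL
  }
  assert_scalar_num(window_ms, "window_ms", positive = TRUE)
  n_block <- round(window_ms * fs / 1000)
  assert_that(n_block >= 1, "`window_ms` converts to < 1 sample")
  assert_that(n_block <= nrow(x),
              "`window_ms` is longer than the analysis window")
  hop <- round(hop_ms * fs / 1000)
  assert_that(hop >= 1, "`hop_ms` converts to < 1 sample")
  starts <- seq(1, nrow(x) - n_block + 1, by = hop)
  vals <- vapply(starts, function(s) {
    sqrt(colMeans(x[s:(s + n_block - 1), , drop = FALSE]^2))
  }, numeric(ncol(x)))
  vals <- matrix(vals, ncol = ncol(x), byrow = TRUE)
  colnames(vals) <- colnames(x)
  structure(list(values = vals,
                 envelope_rate = fs / hop,
                 source_window_ms = window_ms,
                 label = label),
            class = "emg_envelope")
}

#' Peak-dynamic normalization of an envelope
#'
#' Divides each channel by that channel's maximum over the whole analysis
#' window (X_norm = X / X_peak), so values lie in \[0, 1\] and every
#' channel with a positive peak attains 1 exactly. All-zero channels map
#' to zeros rather than erroring, so rest-only windows remain processable
#' in a stream.
#'
#' @param env An `emg_envelope` from [rms_envelope()].
#' @return An `emg_nenv`: dimensionless `values` in \[0, 1\] plus the
#'   per-channel `peak` used.
#' @export
peak_normalize <- function(env) {
  stopifnot(inherits(env, "emg_envelope"))
  assert_that(nrow(env$values) >= 1, "envelope is empty")
  peaks <- apply(env$values, 2, max)
  vals <- env$values
  for (ch in seq_along(peaks)) {
    if (peaks[ch] > 0) vals[, ch] <- vals[, ch] / peaks[ch]
    else vals[, ch] <- 0
  }
  structure(list(values = vals, peak_per_channel = peaks,
                 envelope_rate = env$envelope_rate,
                 source_window_ms = env$source_window_ms,
                 label = env$label),
            class = "emg_nenv")
}
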