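# Protocol-driven synthetic sEMG session generation.
#
# The generator emulates a cue-driven recording session: three forearm
# channels sampled at 1 kHz, randomized task cues of 5 s contraction
# followed by 10 s rest, and three muscle tasks (1 = wrist flexion,
# 2 = fist, 3 = wrist extension). Muscle activity is modelled as
# band-limited (50-150 Hz) noise bursts whose per-channel amplitude
# follows a per-task gain pattern; the fist pattern can be mixed toward
# the flexion/extension patterns to reproduce its confusability.

#' Cue-protocol configuration
#'
#' Describes the recording protocol: sampling rate, contraction and rest
#' durations, repetitions per task and the set of task classes.
#'
#' @param sampling_rate Sampling frequency in Hz.
#' @param task_duration Duration of each cued contraction, seconds.
#' @param rest_duration Rest between cues, seconds.
#' @param repetitions_per_task Number of cues per task class.
#' @param task_classes Integer vector of distinct class ids, in order.
#' @param cue_order `"random"` (seeded shuffle of the cue sequence) or
#'   `"fixed"` (cues grouped in class-id order).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(sampling_rate = 1000, task_duration = 5,
                            rest_duration = 10, repetitions_per_task = 10,
                            task_classes = c(1L, 2L, 3L),
                            cue_order = c("random", "fixed")) {
  cue_order <- match.arg(cue_order)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(task_duration, "task_duration", positive = TRUE)
  assert_scalar_num(rest_duration, "rest_duration", nonneg = TRUE)
  assert_scalar_num(repetitions_per_task, "repetitions_per_task")
  assert_that(repetitions_per_task >= 1, "`repetitions_per_task` must be >= 1")
  assert_that(length(task_classes) >= 1 && !anyDuplicated(task_classes),
              "`task_classes` must be non-empty with distinct ids")
  structure(list(sampling_rate = sampling_rate,
                 task_duration = task_duration,
                 rest_duration = rest_duration,
                 repetitions_per_task = as.integer(repetitions_per_task),
                 task_classes = as.integer(task_classes),
                 cue_order = cue_order),
            class = "protocol_config")
}

#' Signal-generator configuration
#'
#' Parameters of the synthetic sEMG model. Each task has a per-channel
#' amplitude gain pattern (`burst_gain_matrix`, one row per class in
#' `task_classes` order); during a cue, each EMG channel carries
#' band-limited Gaussian noise of RMS amplitude `gain * jitter` on top of
#' baseline noise. `class2_overlap` linearly mixes the second class's row
#' toward the even mixture of rows 1 and 3, reproducing the observed
#' fist/flexion/extension confusability; `amplitude_jitter_sdlog` is the
#' log-sd of the per-event, per-channel lognormal amplitude variability
#' typical of repeated voluntary contractions. IMU columns are constant
#' offsets plus small white noise (they carry no task information).
#'
#' @param n_emg_channels,n_imu_channels Channel counts.
#' @param band Two-element informative frequency band in Hz.
#' @param baseline_noise_sd Standard deviation of baseline noise
#'   (arbitrary sensor-amplified units).
#' @param burst_gain_matrix `length(task_classes) x n_emg_channels`
#'   non-negative matrix; `NULL` uses the built-in 3x3 default.
#' @param class2_overlap Mixing fraction in \[0, 1\] (only used when there
#'   are at least 3 classes).
#' @param amplitude_jitter_sdlog Lognormal sdlog of per-event gains.
#' @param onset_ramp Raised-cosine onset/offset ramp, seconds.
#' @param imu_offsets Length-`n_imu_channels` constant offsets.
#' @param imu_noise_sd White-noise sd of the IMU columns.
#' @param seed Integer generator seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_emg_channels = 3, n_imu_channels = 6,
                             band = c(50, 150), baseline_noise_sd = 0.05,
                             burst_gain_matrix = NULL, class2_overlap = 0.5,
                             amplitude_jitter_sdlog = 0.4,
                             onset_ramp = 0.1,
                             imu_offsets = NULL, imu_noise_sd = 0.01,
                             seed = 1L) {
  assert_that(length(band) == 2 && band[1] > 0 && band[2] > band[1],
              "`band` must be an increasing positive frequency interval")
  assert_that(class2_overlap >= 0 && class2_overlap <= 1,
              "`class2_overlap` must lie in [0, 1]")
  assert_scalar_num(baseline_noise_sd, "baseline_noise_sd", nonneg = TRUE)
  assert_scalar_num(onset_ramp, "onset_ramp", nonneg = TRUE)
  seed <- assert_seed(seed)
  if (is.null(imu_offsets)) {
    imu_offsets <- rep(c(0, 0, 1, 0, 0, 0), length.out = n_imu_channels)
  }
  assert_that(length(imu_offsets) == n_imu_channels,
              "`imu_offsets` length must equal `n_imu_channels`")
  structure(list(n_emg_channels = as.integer(n_emg_channels),
                 n_imu_channels = as.integer(n_imu_channels),
                 band = as.numeric(band),
                 baseline_noise_sd = baseline_noise_sd,
                 burst_gain_matrix = burst_gain_matrix,
                 class2_overlap = class2_overlap,
                 amplitude_jitter_sdlog = amplitude_jitter_sdlog,
                 onset_ramp = onset_ramp,
                 imu_offsets = as.numeric(imu_offsets),
                 imu_noise_sd = imu_noise_sd,
                 seed = seed),
            class = "generator_config")
}

# Default per-task channel-gain patterns for 3 classes x 3 channels:
# flexion dominant on channel 1 (flexor), fist on channel 2, extension on
# channel 3 (extensor); weak co-activation of the middle channel for the
# wrist tasks. Rows in task_classes order.
default_gain_matrix <- function(n_classes, n_channels) {
  if (n_classes == 3 && n_channels == 3) {
    matrix(c(1.00, 0.15, 0.00,
             0.00, 1.00, 0.00,
             0.00, 0.15, 1.00),
           nrow = 3, byrow = TRUE)
  } else {
    # generic fallback: class k dominant on channel (k mod n_channels)
    g <- matrix(0.1, n_classes, n_channels)
    for (k in seq_len(n_classes)) g[k, ((k - 1) %% n_channels) + 1] <- 1
    g
  }
}

# Resolve the effective gain matrix, applying the class-2 overlap mix.
effective_gain_matrix <- function(gen, protocol) {
  n_cls <- length(protocol$task_classes)
  g <- gen$burst_gain_matrix %||%
    default_gain_matrix(n_cls, gen$n_emg_channels)
  g <- as.matrix(g)
  assert_that(nrow(g) == n_cls && ncol(g) == gen$n_emg_channels,
              "gain matrix shape must be |task_classes| x n_emg_channels")
  assert_that(all(g >= 0), "gain matrix entries must be >= 0")
  if (n_cls >= 3 && gen$class2_overlap > 0) {
    ov <- gen$class2_overlap
    g[2, ] <- (1 - ov) * g[2, ] + ov * (g[1, ] + g[3, ]) / 2
  }
  g
}

#' Build a cue schedule
#'
#' Lays out `repetitions_per_task` cues per class, each `task_duration`
#' seconds long and separated by `rest_duration` seconds of rest. With
#' `cue_order = "random"` the cue sequence is a seeded shuffle; with
#' `"fixed"` cues are grouped in class-id order.
#'
#' @param protocol A [protocol_config()].
#' @param seed Integer seed for the cue shuffle.
#' @return An `event_schedule` data.frame with columns `class`, `onset`,
#'   `offset` (seconds).
#' @export
build_schedule <- function(protocol, seed = 1L) {
  stopifnot(inherits(protocol, "protocol_config"))
  seed <- assert_seed(seed)
  classes <- rep(protocol$task_classes, each = protocol$repetitions_per_task)
  if (protocol$cue_order == "random") {
    classes <- withr::with_seed(
      seed, classes[sample.int(length(classes))])
  }
  n <- length(classes)
  onset <- (seq_len(n) - 1) * (protocol$task_duration + protocol$rest_duration)
  sched <- data.frame(class = as.integer(classes),
                      onset = onset,
                      offset = onset + protocol$task_duration)
  class(sched) <- c("event_schedule", "data.frame")
  sched
}

# Band-limited unit-RMS Gaussian noise via FFT masking. Bins whose
# frequency (or alias) falls inside [band[1], band[2]] are kept.
bandlimited_noise <- function(n, fs, band) {
  if (n < 4) return(numeric(n))
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # fold to [0, fs/2]
  mask <- f >= band[1] & f <= band[2]
  if (!any(mask)) stop("band contains no resolvable frequency bins",
                       call. = FALSE)
  y <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

# Raised-cosine on/off envelope for a burst of n samples.
burst_envelope <- function(n, fs, ramp_s) {
  env <- rep(1, n)
  r <- min(floor(ramp_s * fs), floor(n / 2))
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- up
    env[n + 1 - seq_len(r)] <- up
  }
  env
}

#' Synthesize a session recording from a schedule
#'
#' Renders a multichannel recording: baseline Gaussian noise on every EMG
#' channel, band-limited bursts during each scheduled event scaled by that
#' class's gain pattern (with per-event lognormal amplitude jitter), and
#' near-constant IMU columns. Fully reproducible from `gen$seed`.
#'
#' @param schedule An `event_schedule` from [build_schedule()].
#' @param protocol The matching [protocol_config()].
#' @param gen A [generator_config()].
#' @return An `emg_recording` (see [recording()]), unlabeled.
#' @export
synthesize_recording <- function(schedule, protocol, gen) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(protocol, "protocol_config"),
            inherits(gen, "generator_config"))
  fs <- protocol$sampling_rate
  assert_that(gen$band[2] < fs / 2,
              "configuration error: band exceeds the Nyquist limit fs/2")
  gains <- effective_gain_matrix(gen, protocol)
  total_s <- max(schedule$offset) + protocol$rest_duration
  n <- round(total_s * fs)
  withr::with_seed(gen$seed, {
    emg <- matrix(stats::rnorm(n * gen$n_emg_channels,
                               sd = gen$baseline_noise_sd),
                  nrow = n, ncol = gen$n_emg_channels)
    for (ev in seq_len(nrow(schedule))) {
      cls_idx <- match(schedule$class[ev], protocol$task_classes)
      i0 <- round(schedule$onset[ev] * fs) + 1
      i1 <- min(round(schedule$offset[ev] * fs), n)
      len <- i1 - i0 + 1
      if (len <= 0) next
      ramp <- burst_envelope(len, fs, gen$onset_ramp)
      for (ch in seq_len(gen$n_emg_channels)) {
        g <- gains[cls_idx, ch]
        if (g <= 0) next
        jit <- stats::rlnorm(1, meanlog = 0,
                             sdlog = gen$amplitude_jitter_sdlog)
        emg[i0:i1, ch] <- emg[i0:i1, ch] +
          g * jit * ramp * bandlimited_noise(len, fs, gen$band)
      }
    }
    imu <- matrix(stats::rnorm(n * gen$n_imu_channels, sd = gen$imu_noise_sd),
                  nrow = n, ncol = gen$n_imu_channels)
    imu <- sweep(imu, 2, gen$imu_offsets, `+`)
  })
  recording(emg = emg, imu = imu, sampling_rate = fs)
}

#' Generate a labeled single-task dataset on disk
#'
#' Writes `n_trials_per_task` single-task recording files per class in the
#' dataset CSV layout (one labeled task window per file, label encoded in
#' the filename) plus a `manifest.csv` listing file, class and seed.
#'
#' @param protocol A [protocol_config()]; its `task_duration` sets the
#'   per-file recording length.
#' @param gen A [generator_config()]; per-file seeds are derived from
#'   `gen$seed`.
#' @param n_trials_per_task Files per class.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (`file`, `class`, `seed`).
#' @export
generate_dataset <- function(protocol, gen, n_trials_per_task = 20,
                             out_dir) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(gen, "generator_config"))
  assert_that(n_trials_per_task >= 1, "`n_trials_per_task` must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir),
              sprintf("cannot create output directory '%s'", out_dir))
  single <- protocol
  single$repetitions_per_task <- 1L
  rows <- list()
  i <- 0L
  for (cls in protocol$task_classes) {
    one <- single
    one$task_classes <- cls
    sched <- build_schedule(one, seed = 0L)  # single event at t = 0
    for (trial in seq_len(n_trials_per_task)) {
      i <- i + 1L
      g <- gen
      g$seed <- derive_seed(gen$seed, i)
      rec <- synthesize_recording(sched, one, g)
      # keep only the task window itself: one file = one labeled task
      keep <- seq_len(round(protocol$task_duration * protocol$sampling_rate))
      rec$emg <- rec$emg[keep, , drop = FALSE]
      rec$imu <- rec$imu[keep, , drop = FALSE]
      rec$label <- as.integer(cls)
      rec$trial_id <- sprintf("t%02d", trial)
      path <- write_recording(rec, out_dir)
      rows[[i]] <- data.frame(file = basename(path),
                              class = as.integer(cls), seed = g$seed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
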