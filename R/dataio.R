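# Recording I/O in the dataset's CSV layout and window segmentation.
#
# One CSV file holds one recording: a header row with stable column names
# (emg1..emgK, then acc1..acc3/gyr1..gyr3 for the inertial columns), one
# row per sample. The class label is carried in the filename as
# class<k>_<trial_id>.csv, not in a column.

#' Construct a multichannel recording
#'
#' @param emg Numeric matrix, samples x EMG channels.
#' @param imu Numeric matrix, samples x inertial channels (same row count).
#' @param sampling_rate Sampling frequency in Hz.
#' @param label Optional integer class id.
#' @param trial_id Optional trial identifier string.
#' @return An `emg_recording` list.
#' @export
recording <- function(emg, imu, sampling_rate, label = NULL,
                      trial_id = "t01") {
  emg <- as.matrix(emg); imu <- as.matrix(imu)
  assert_that(nrow(emg) == nrow(imu),
              "emg and imu must have equal row counts")
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.null(label)) label <- as.integer(label)
  structure(list(emg = emg, imu = imu, sampling_rate = sampling_rate,
                 label = label, trial_id = as.character(trial_id)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "emg_recording: %d samples x (%d EMG + %d IMU) @ %g Hz (%.2f s)%s\n",
    nrow(x$emg), ncol(x$emg), ncol(x$imu), x$sampling_rate,
    nrow(x$emg) / x$sampling_rate,
    if (is.null(x$label)) "" else sprintf(", class %d", x$label)))
  invisible(x)
}

recording_colnames <- function(n_emg, n_imu) {
  imu_names <- if (n_imu == 6) {
    c(paste0("acc", 1:3), paste0("gyr", 1:3))
  } else {
    paste0("imu", seq_len(n_imu))
  }
  c(paste0("emg", seq_len(n_emg)), imu_names)
}

#' Write a recording as CSV
#'
#' The file is named `class<k>_<trial_id>.csv` when the recording is
#' labeled, `<trial_id>.csv` otherwise.
#'
#' @param rec An `emg_recording`.
#' @param dir Output directory.
#' @return The path written.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "emg_recording"))
  fname <- if (is.null(rec$label)) {
    sprintf("%s.csv", rec$trial_id)
  } else {
    sprintf("class%d_%s.csv", rec$label, rec$trial_id)
  }
  path <- file.path(dir, fname)
  tab <- cbind(rec$emg, rec$imu)
  colnames(tab) <- recording_colnames(ncol(rec$emg), ncol(rec$imu))
  data.table::fwrite(data.table::as.data.table(tab), path)
  path
}

#' Read a recording from CSV
#'
#' Columns named `emg*` are taken as EMG channels and the remainder as
#' inertial columns. A `class<k>_` filename prefix is recovered as the
#' label. Headerless files are supported via `header = FALSE` together
#' with `n_emg` to fix the column split.
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling frequency of the stored signal, Hz.
#' @param header Whether the file carries a header row.
#' @param n_emg Number of leading EMG columns when `header = FALSE`.
#' @return An `emg_recording`.
#' @export
read_recording <- function(path, sampling_rate = 1000, header = TRUE,
                           n_emg = 3) {
  assert_that(file.exists(path), sprintf("file '%s' does not exist", path))
  # let fread finish (and clean up) before promoting its warnings
  parse_warning <- NULL
  tab <- tryCatch(
    withCallingHandlers(
      data.table::fread(path, header = header, data.table = FALSE),
      warning = function(w) {
        parse_warning <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop(sprintf(
      "parse error in '%s': %s", path, conditionMessage(e)), call. = FALSE))
  if (!is.null(parse_warning)) {
    stop(sprintf("parse error in '%s': %s", path, parse_warning),
         call. = FALSE)
  }
  if (!all(vapply(tab, is.numeric, logical(1)))) {
    bad <- names(tab)[!vapply(tab, is.numeric, logical(1))][1]
    stop(sprintf("parse error in '%s': non-numeric field '%s'", path, bad),
         call. = FALSE)
  }
  if (header) {
    emg_cols <- grep("^emg", names(tab))
    assert_that(length(emg_cols) >= 1,
                sprintf("parse error in '%s': no emg* columns in header",
                        path))
  } else {
    emg_cols <- seq_len(min(n_emg, ncol(tab)))
  }
  fname <- basename(path)
  label <- NULL
  trial_id <- sub("\\.csv$", "", fname)
  m <- regmatches(fname, regexec("^class([0-9]+)_(.*)\\.csv$", fname))[[1]]
  if (length(m) == 3) {
    label <- as.integer(m[2])
    trial_id <- m[3]
  } else if (grepl("^class", fname)) {
    stop(sprintf("unknown class token in filename '%s'", fname),
         call. = FALSE)
  }
  recording(emg = as.matrix(tab[, emg_cols, drop = FALSE]),
            imu = as.matrix(tab[, -emg_cols, drop = FALSE]),
            sampling_rate = sampling_rate, label = label,
            trial_id = trial_id)
}

#' Construct an analysis window
#'
#' The fixed-duration EMG slice on which one classification decision is
#' made (2 s by default throughout the pipeline).
#'
#' @param samples Numeric matrix, window samples x EMG channels.
#' @param sampling_rate Hz.
#' @param label Optional class id.
#' @return An `emg_window` list with `duration` in seconds.
#' @export
analysis_window <- function(samples, sampling_rate, label = NULL) {
  samples <- as.matrix(samples)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 duration = nrow(samples) / sampling_rate,
                 label = if (is.null(label)) NULL else as.integer(label)),
            class = "emg_window")
}

#' Segment a session recording into labeled analysis windows
#'
#' One window per scheduled event, anchored at the event onset (the
#' informative part of a contraction is its activation) and labeled with
#' the event class. EMG channels only.
#'
#' @param rec An `emg_recording`.
#' @param schedule An `event_schedule`.
#' @param window_duration Window length in seconds; must not exceed the
#'   event duration.
#' @return List of `emg_window` objects, in schedule order.
#' @export
segment_recording <- function(rec, schedule, window_duration) {
  stopifnot(inherits(rec, "emg_recording"),
            inherits(schedule, "event_schedule"))
  assert_scalar_num(window_duration, "window_duration", positive = TRUE)
  durs <- schedule$offset - schedule$onset
  assert_that(all(window_duration <= durs + 1e-9),
              "`window_duration` must not exceed the event duration")
  fs <- rec$sampling_rate
  wlen <- round(window_duration * fs)
  lapply(seq_len(nrow(schedule)), function(ev) {
    i0 <- round(schedule$onset[ev] * fs) + 1
    i1 <- i0 + wlen - 1
    if (i1 > nrow(rec$emg)) {
      stop(sprintf(
        "window for event %d (class %d, onset %g s) extends past the end of the recording",
        ev, schedule$class[ev], schedule$onset[ev]), call. = FALSE)
    }
    analysis_window(rec$emg[i0:i1, , drop = FALSE], fs,
                    label = schedule$class[ev])
  })
}

#' Load a generated dataset directory as analysis windows
#'
#' Reads every file listed in `manifest.csv` and returns one window per
#' file, truncated to `window_duration` seconds from the file start.
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @param window_duration Seconds per window.
#' @param sampling_rate Hz of the stored recordings.
#' @return List of labeled `emg_window` objects.
#' @export
load_dataset_windows <- function(dir, window_duration = 2,
                                 sampling_rate = 1000) {
  man_path <- file.path(dir, "manifest.csv")
  assert_that(file.exists(man_path),
              sprintf("no manifest.csv in '%s'", dir))
  manifest <- utils::read.csv(man_path)
  wlen <- round(window_duration * sampling_rate)
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_recording(file.path(dir, manifest$file[i]),
                          sampling_rate = sampling_rate)
    assert_that(nrow(rec$emg) >= wlen, sprintf(
      "file '%s' is shorter than the requested window", manifest$file[i]))
    analysis_window(rec$emg[seq_len(wlen), , drop = FALSE], sampling_rate,
                    label = rec$label)
  })
}
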