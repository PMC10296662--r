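# Confidence-gated streaming classification and virtual actuation.
#
# The on-device loop buffers consecutive non-overlapping 2 s windows from
# the sample stream, runs the feature/classify chain on each, suppresses
# any prediction whose confidence is not strictly greater than the 0.70
# gate, and maps the surviving class to a motor command:
#   class 1 (wrist flexion)   -> gripper +20 deg (clockwise, close)
#   class 2 (fist)            -> turn base +30 deg (clockwise)
#   class 3 (wrist extension) -> gripper -20 deg (counterclockwise, open)

#' Map a prediction to a motor command
#'
#' @param pred An `emg_prediction`.
#' @param threshold Confidence gate; commands are emitted only when
#'   `confidence > threshold` (strict).
#' @return A `motor_command` (`target`, `delta_angle` in degrees with
#'   positive = clockwise, `cause` class id), or `NULL` when gated.
#' @export
map_prediction <- function(pred, threshold = 0.70) {
  stopifnot(inherits(pred, "emg_prediction"))
  if (!(pred$confidence > threshold)) return(NULL)
  cmd <- switch(as.character(pred$class),
                "1" = list(target = "gripper", delta_angle = 20),
                "2" = list(target = "base", delta_angle = 30),
                "3" = list(target = "gripper", delta_angle = -20),
                stop(sprintf("unknown class id %s", pred$class),
                     call. = FALSE))
  structure(c(cmd, list(cause = pred$class)), class = "motor_command")
}

#' Virtual prosthesis state
#'
#' Angles of the two actuated axes plus their hard limits; every update
#' clamps into the limits.
#'
#' @param gripper_angle,base_angle Initial angles, degrees.
#' @param gripper_limits,base_limits Closed angle intervals.
#' @return A `prosthetic_state`.
#' @export
prosthetic_state <- function(gripper_angle = 45, base_angle = 90,
                             gripper_limits = c(0, 90),
                             base_limits = c(0, 180)) {
  clamp <- function(x, lim) min(max(x, lim[1]), lim[2])
  structure(list(gripper_angle = clamp(gripper_angle, gripper_limits),
                 base_angle = clamp(base_angle, base_limits),
                 gripper_limits = gripper_limits,
                 base_limits = base_limits),
            class = "prosthetic_state")
}

#' Apply a motor command to the prosthesis state
#'
#' @param state A [prosthetic_state()].
#' @param cmd A `motor_command`, or `NULL` (no-op).
#' @return The updated state; angles stay within the limits.
#' @export
apply_command <- function(state, cmd) {
  stopifnot(inherits(state, "prosthetic_state"))
  if (is.null(cmd)) return(state)
  stopifnot(inherits(cmd, "motor_command"))
  clamp <- function(x, lim) min(max(x, lim[1]), lim[2])
  if (cmd$target == "gripper") {
    state$gripper_angle <- clamp(state$gripper_angle + cmd$delta_angle,
                                 state$gripper_limits)
  } else {
    state$base_angle <- clamp(state$base_angle + cmd$delta_angle,
                              state$base_limits)
  }
  state
}

#' Streaming classification of a sample stream
#'
#' Cuts the stream into consecutive windows of `window_duration`
#' (non-overlapping by default; `hop_duration` allows a sliding hop),
#' featurizes each with the subwindow-RMS chain, classifies it, applies
#' the confidence gate and actuates the virtual prosthesis in order. The
#' trailing partial window is discarded. Deterministic given the stream
#' and model.
#'
#' @param stream An `emg_recording`, or samples x channels matrix (then
#'   `sampling_rate` is required).
#' @param model A trained `mlp_model`.
#' @param config A [pipeline_config()] (feature settings).
#' @param window_duration Decision window, seconds.
#' @param threshold Confidence gate.
#' @param state Initial [prosthetic_state()].
#' @param hop_duration Hop between decision windows, seconds.
#' @param sampling_rate Hz, for matrix input.
#' @return A `stream_log`: data.frame `steps` (window, time, class,
#'   confidence, target, delta_angle, gripper_angle, base_angle) plus
#'   `predictions`, `commands` and `final_state`.
#' @export
stream_classify <- function(stream, model, config = pipeline_config(),
                            window_duration = 2, threshold = 0.70,
                            state = prosthetic_state(),
                            hop_duration = window_duration,
                            sampling_rate = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  if (inherits(stream, "emg_recording")) {
    x <- stream$emg
    fs <- stream$sampling_rate
  } else {
    x <- as.matrix(stream)
    assert_that(!is.null(sampling_rate),
                "`sampling_rate` is required for matrix input")
    fs <- sampling_rate
  }
  wlen <- round(window_duration * fs)
  hop <- round(hop_duration * fs)
  assert_that(wlen >= 1 && hop >= 1, "window and hop must be >= 1 sample")
  n_steps <- if (nrow(x) >= wlen) floor((nrow(x) - wlen) / hop) + 1 else 0
  starts <- (seq_len(n_steps) - 1) * hop + 1
  preds <- vector("list", length(starts))
  cmds <- vector("list", length(starts))
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    win <- analysis_window(x[starts[i]:(starts[i] + wlen - 1), ,
                             drop = FALSE], fs)
    feats <- extract_features(win, method = "rms",
                              window_ms = config$window_ms,
                              subwindow_ms = config$subwindow_ms)
    pred <- predict_mlp(model, feats)
    cmd <- map_prediction(pred, threshold = threshold)
    state <- apply_command(state, cmd)
    preds[[i]] <- pred
    cmds[i] <- list(cmd)
    rows[[i]] <- data.frame(
      window = i, time = (starts[i] - 1) / fs,
      class = pred$class, confidence = pred$confidence,
      target = if (is.null(cmd)) NA_character_ else cmd$target,
      delta_angle = if (is.null(cmd)) NA_real_ else cmd$delta_angle,
      gripper_angle = state$gripper_angle, base_angle = state$base_angle)
  }
  steps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window = integer(0), time = numeric(0), class = integer(0),
               confidence = numeric(0), target = character(0),
               delta_angle = numeric(0), gripper_angle = numeric(0),
               base_angle = numeric(0))
  structure(list(steps = steps, predictions = preds,
                 commands = cmds, final_state = state),
            class = "stream_log")
}
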