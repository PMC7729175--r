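#' Interface-controller configuration
#'
#' Evidence thresholds of the online selection rule: per option, only the
#' last `window` artifact-free flash labels are kept; an option is selected
#' once it has at least `min_epochs` buffered labels, at least
#' `target_threshold` of them are `target`, and every other option with at
#' least one buffered label is labeled `non-target` at least
#' `nontarget_threshold` of the time. With the defaults (0.70/0.60) the two
#' thresholds sum to more than 1, which makes a selection unique: an option
#' at >= 70% target is at <= 30% non-target and therefore vetoes all others.
#'
#' @param window Ring-buffer capacity per option.
#' @param min_epochs Minimum buffered labels before an option is eligible.
#' @param target_threshold Minimum target fraction of the selected option.
#' @param nontarget_threshold Minimum non-target fraction of every other
#'   option with buffered labels.
#' @param n_c Number of flashing options.
#' @param selection_pause_s Pause after a selection while the orthosis moves.
#' @param attempt_timeout_s Flashing time allowed per selection attempt.
#' @param rest_s Rest between attempts.
#' @return Named list of class `bmi_controller_config`.
#' @export
controller_config <- function(window = 10, min_epochs = 5,
                              target_threshold = 0.70,
                              nontarget_threshold = 0.60,
                              n_c = 6, selection_pause_s = 4,
                              attempt_timeout_s = 30, rest_s = 5) {
  if (min_epochs > window) {
    stop_parameter("min_epochs must not exceed window")
  }
  if (target_threshold <= 0.5 || target_threshold > 1 ||
      nontarget_threshold <= 0.5 || nontarget_threshold > 1) {
    stop_parameter("thresholds must lie in (0.5, 1]")
  }
  structure(
    list(window = window, min_epochs = min_epochs,
         target_threshold = target_threshold,
         nontarget_threshold = nontarget_threshold,
         n_c = n_c, selection_pause_s = selection_pause_s,
         attempt_timeout_s = attempt_timeout_s, rest_s = rest_s),
    class = c("bmi_controller_config", "list")
  )
}

#' Create a fresh controller state
#'
#' @param config A [controller_config()].
#' @return Object of class `bmi_controller`: one empty label buffer per
#'   option (logical vectors, TRUE = target), a discarded-artifact counter,
#'   and the configuration.
#' @export
new_controller <- function(config = controller_config()) {
  structure(
    list(buffers = rep(list(logical(0)), config$n_c),
         discarded = 0L,
         config = config),
    class = "bmi_controller"
  )
}

#' Feed one flash label to the controller
#'
#' Artifact labels only increment the discard counter. A valid label is
#' pushed into the flashed option's ring buffer (evicting the oldest entry
#' beyond the window), after which the selection conditions are evaluated
#' over all options. Options with empty buffers cannot veto a selection.
#'
#' @param state A `bmi_controller`.
#' @param option_id Flashed option, in `[0, n_c)`.
#' @param label `"target"`, `"non-target"`, or `"artifact"`.
#' @return List with the updated `state` and a `decision` (list with `kind`
#'   of `"none"`/`"select"`, `option_id` when selecting, and the per-option
#'   `evidence` counts at decision time).
#' @export
controller_update <- function(state, option_id, label) {
  stopifnot(inherits(state, "bmi_controller"))
  cfg <- state$config
  if (option_id < 0 || option_id >= cfg$n_c) {
    stop_parameter(sprintf("option_id %d outside [0, %d)", option_id, cfg$n_c))
  }
  if (!label %in% c("target", "non-target", "artifact")) {
    stop_parameter(sprintf("unknown label '%s'", label))
  }
  if (label == "artifact") {
    state$discarded <- state$discarded + 1L
    return(list(state = state, decision = list(kind = "none")))
  }
  buf <- c(state$buffers[[option_id + 1L]], label == "target")
  if (length(buf) > cfg$window) {
    buf <- buf[(length(buf) - cfg$window + 1L):length(buf)]
  }
  state$buffers[[option_id + 1L]] <- buf

  evidence <- data.frame(
    option_id = seq_len(cfg$n_c) - 1L,
    n = vapply(state$buffers, length, integer(1)),
    n_target = vapply(state$buffers, sum, integer(1))
  )
  evidence$frac_target <- ifelse(evidence$n > 0,
                                 evidence$n_target / evidence$n, NA_real_)

  selected <- NA_integer_
  for (o in seq_len(cfg$n_c)) {
    n_o <- evidence$n[o]
    if (n_o < cfg$min_epochs) next
    if (evidence$frac_target[o] < cfg$target_threshold) next
    others <- evidence[-o, , drop = FALSE]
    others <- others[others$n > 0, , drop = FALSE]
    if (nrow(others) &&
        any(1 - others$frac_target < cfg$nontarget_threshold)) next
    selected <- evidence$option_id[o]
    break
  }
  if (is.na(selected)) {
    list(state = state, decision = list(kind = "none", evidence = evidence))
  } else {
    # after a selection all buffers reset; flashing pauses for the movement
    state$buffers <- rep(list(logical(0)), cfg$n_c)
    list(state = state,
         decision = list(kind = "select", option_id = selected,
                         evidence = evidence))
  }
}

#' Run one selection attempt over a timed label stream
#'
#' Feeds `(option_id, label)` events to the controller in time order until a
#' selection fires or `attempt_timeout_s` of flashing elapses. The selection
#' time is measured from the start of flashing (time 0 of the stream) to the
#' deciding event.
#'
#' @param stream Data frame with columns `time_s` (non-decreasing),
#'   `option_id`, `label`.
#' @param config A [controller_config()].
#' @return List of class `bmi_attempt`: `kind` (`"select"`/`"timeout"`),
#'   `option_id` (NA on timeout), `selection_time_s`, `n_events`,
#'   `n_artifacts`.
#' @export
run_attempt <- function(stream, config = controller_config()) {
  if (nrow(stream) && is.unsorted(stream$time_s)) {
    stop_validation("stream timestamps must be non-decreasing")
  }
  state <- new_controller(config)
  if (nrow(stream)) {
    for (i in seq_len(nrow(stream))) {
      if (stream$time_s[i] > config$attempt_timeout_s) break
      res <- controller_update(state, stream$option_id[i], stream$label[i])
      state <- res$state
      if (res$decision$kind == "select") {
        return(structure(
          list(kind = "select", option_id = res$decision$option_id,
               selection_time_s = stream$time_s[i],
               n_events = i, n_artifacts = state$discarded),
          class = "bmi_attempt"))
      }
    }
  }
  structure(
    list(kind = "timeout", option_id = NA_integer_,
         selection_time_s = NA_real_,
         n_events = nrow(stream), n_artifacts = state$discarded),
    class = "bmi_attempt")
}

FINGERS <- c("thumb", "index", "middle", "ring", "little")

#' Map a selected option to an orthosis movement plan
#'
#' Options 0-4 drive the flexion-extension of a single digit (thumb through
#' little finger); option 5 flexes and extends all five digits
#' simultaneously. Every plan lasts 4 s, matching the pause of the flashing
#' sequence while the orthosis moves.
#'
#' @param option_id Integer in `[0, 6)`.
#' @param duration_s Movement duration in seconds.
#' @return List of class `bmi_movement`: `option_id`, `actuators`, `action`,
#'   `duration_s`.
#' @export
plan_movement <- function(option_id, duration_s = 4) {
  if (!is.numeric(option_id) || length(option_id) != 1 ||
      is.na(option_id) || option_id < 0 || option_id > 5 ||
      option_id != round(option_id)) {
    stop_parameter("option_id must be an integer in [0, 5]")
  }
  actuators <- if (option_id == 5) FINGERS else FINGERS[option_id + 1]
  structure(
    list(option_id = as.integer(option_id), actuators = actuators,
         action = "flexion-extension", duration_s = duration_s),
    class = "bmi_movement"
  )
}

#' Expand a movement plan into motor-position command frames
#'
#' Emits a per-motor position sequence (0 = extended, 1 = flexed) sampled at
#' `rate_hz`, one raised-cosine flexion-extension cycle over the plan
#' duration, mirroring a wireless motor-position command channel. No device
#' I/O is performed.
#'
#' @param plan A [plan_movement()] result.
#' @param rate_hz Command frame rate.
#' @return Data frame: `time_s` plus one position column per finger
#'   (inactive fingers stay at 0).
#' @export
movement_frames <- function(plan, rate_hz = 10) {
  stopifnot(inherits(plan, "bmi_movement"))
  t <- seq(0, plan$duration_s, by = 1 / rate_hz)
  cycle <- 0.5 * (1 - cos(2 * pi * t / plan$duration_s))
  frames <- data.frame(time_s = t)
  for (f in FINGERS) {
    frames[[f]] <- if (f %in% plan$actuators) cycle else 0
  }
  frames
}
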