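#' Repetition-segmentation state
#'
#' Hysteresis state machine that turns the progress-sample stream into
#' counted repetitions. Phases advance only along
#' idle -> advancing -> returning -> idle: a repetition begins when
#' progress leaves the start region (>= `low_threshold`), its peak is
#' tracked while advancing, the return phase starts once progress drops a
#' hysteresis band below the peak, and the repetition completes (an event
#' is emitted) when progress re-enters the start region. Deviation samples
#' (-1) are ignored for phase logic, but a deviation sustained longer than
#' `deviation_reset_s` resets the current peak.
#'
#' @param exercise_id Identifier stored on emitted events.
#' @param low_threshold Progress at/below which the hand is in the start
#'   region; default 0.15.
#' @param hysteresis Drop below the running peak that switches to the
#'   returning phase; default 0.1.
#' @param deviation_reset_s Seconds of sustained deviation after which the
#'   running peak is discarded; default 1.
#' @return A `rep_state` object.
#' @export
rep_state <- function(exercise_id = "exercise", low_threshold = 0.15,
                      hysteresis = 0.1, deviation_reset_s = 1) {
  stopifnot(low_threshold > 0, low_threshold < 1, hysteresis > 0)
  structure(list(exercise_id = exercise_id, phase = "idle",
                 low_threshold = low_threshold, hysteresis = hysteresis,
                 deviation_reset_s = deviation_reset_s,
                 peak = 0, start_time = NA_real_, deviating_since = NA_real_,
                 n_events = 0L, n_recognized = 0L),
            class = "rep_state")
}

#' Feed one progress sample through the repetition state machine
#'
#' @param state A [rep_state()].
#' @param timestamp Sample time, seconds (samples must arrive in order).
#' @param value Progress sample: in \[0, 1\] or -1.
#' @param target Recognition target in (0, 1\]: the repetition is
#'   "recognized" (counts toward station quotas) iff its peak reaches the
#'   target. May be a `rom_target` object or a bare number.
#' @return List with `state` (updated) and `event` (`NULL`, or a one-row
#'   data frame with `exercise_id`, `start_time`, `end_time`, `duration`,
#'   `peak_progress`, `recognized` when a repetition completed).
#' @export
update_repetition <- function(state, timestamp, value, target) {
  tgt <- if (inherits(target, "rom_target")) target$target else target
  stopifnot(is_number(tgt), tgt > 0, tgt <= 1)
  ev <- NULL
  if (value < 0) {                      # deviation: pause, maybe reset peak
    if (is.na(state$deviating_since)) state$deviating_since <- timestamp
    if (timestamp - state$deviating_since > state$deviation_reset_s)
      state$peak <- 0
    return(list(state = state, event = NULL))
  }
  state$deviating_since <- NA_real_
  if (state$phase == "idle") {
    if (value >= state$low_threshold) {
      state$phase <- "advancing"
      state$start_time <- timestamp
      state$peak <- value
    }
  } else if (state$phase == "advancing") {
    if (value > state$peak) state$peak <- value
    if (value < state$peak - state$hysteresis) state$phase <- "returning"
  } else {                              # returning
    if (value >= state$peak) {          # re-advance within the same excursion
      state$phase <- "advancing"
      state$peak <- value
    }
  }
  if (state$phase == "returning" && value <= state$low_threshold) {
    recognized <- state$peak >= tgt
    ev <- data.frame(exercise_id = state$exercise_id,
                     start_time = state$start_time, end_time = timestamp,
                     duration = timestamp - state$start_time,
                     peak_progress = state$peak, recognized = recognized,
                     stringsAsFactors = FALSE)
    state$n_events <- state$n_events + 1L
    state$n_recognized <- state$n_recognized + (recognized)
    state$phase <- "idle"
    state$peak <- 0
    state$start_time <- NA_real_
  }
  list(state = state, event = ev)
}

#' Segment a whole progress-sample series into repetitions
#'
#' @param timestamps,values Numeric vectors of equal length (seconds;
#'   progress in \[0,1\] or -1).
#' @inheritParams update_repetition
#' @param ... Passed to [rep_state()].
#' @return Data frame of repetition events (possibly zero rows).
#' @export
segment_repetitions <- function(timestamps, values, target,
                                exercise_id = "exercise", ...) {
  stopifnot(length(timestamps) == length(values))
  st <- rep_state(exercise_id = exercise_id, ...)
  evs <- vector("list", 32L)
  k <- 0L
  for (i in seq_along(values)) {
    res <- update_repetition(st, timestamps[i], values[i], target)
    st <- res$state
    if (!is.null(res$event)) {
      k <- k + 1L
      if (k > length(evs)) evs <- c(evs, vector("list", length(evs)))
      evs[[k]] <- res$event
    }
  }
  if (k == 0L)
    return(data.frame(exercise_id = character(), start_time = numeric(),
                      end_time = numeric(), duration = numeric(),
                      peak_progress = numeric(), recognized = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, evs[seq_len(k)])
}

#' Track an exercise over a motion stream
#'
#' Composes feature extraction, the path-progress mapping and repetition
#' segmentation over a stream: the full pipeline the game runs per frame.
#' Deterministic for a fixed stream.
#'
#' @param stream A list of [tracked_frame()]s, a `motion_stream` from the
#'   simulator, or a numeric feature matrix (with a `timestamps` attribute
#'   or accompanied by `timestamps`).
#' @param exercise An [define_exercise()] definition.
#' @param target Recognition target (see [update_repetition()]).
#' @param side Hand to track for single-hand exercises.
#' @param timestamps Optional numeric vector when `stream` is a bare matrix.
#' @param ... Passed to [rep_state()].
#' @return List with `samples` (data frame `timestamp`, `value`) and
#'   `events` (data frame of repetitions).
#' @export
track_exercise <- function(stream, exercise, target, side = "right",
                           timestamps = NULL, ...) {
  if (inherits(stream, "motion_stream")) {
    X <- stream$features
    ts <- stream$timestamps
  } else if (is.matrix(stream)) {
    X <- stream
    ts <- if (!is.null(timestamps)) timestamps else attr(stream, "timestamps")
    if (is.null(ts))
      hr_stop("matrix streams need timestamps", "handrehab_bad_argument")
  } else {
    if (!length(stream))
      hr_stop("stream is empty", "handrehab_bad_argument")
    ts_all <- vapply(stream, `[[`, numeric(1), "timestamp")
    if (any(diff(ts_all) <= 0))
      hr_stop("timestamps must be strictly increasing", "handrehab_bad_frame")
    keep <- vapply(stream, function(fr) !is.null(fr[[side]]), logical(1))
    X <- stream_features(stream[keep], exercise$channels, side)
    ts <- ts_all[keep]
  }
  vals <- progress_stream(X, exercise)
  events <- segment_repetitions(ts, vals, target,
                                exercise_id = exercise$id, ...)
  list(samples = data.frame(timestamp = ts, value = vals),
       events = events)
}
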