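#' Per-day record of achieved range of motion
#'
#' @param exercise_id Exercise the peaks belong to.
#' @param day Protocol day (positive integer).
#' @param peaks Per-repetition peak progress values in (0, 1].
#' @return A `rom_record` object.
#' @export
rom_record <- function(exercise_id, day, peaks) {
  if (!is_number(day) || day < 1)
    hr_stop("day must be a positive integer", "handrehab_bad_argument")
  peaks <- as.numeric(peaks)
  if (!length(peaks) || any(!is.finite(peaks)) || any(peaks <= 0) ||
      any(peaks > 1 + 1e-12))
    hr_stop("peaks must be a non-empty vector in (0, 1]", "handrehab_bad_argument")
  structure(list(exercise_id = as.character(exercise_id),
                 day = as.integer(day), peaks = pmin(peaks, 1)),
            class = "rom_record")
}

#' Measure a player's initial range of motion
#'
#' On first encountering an exercise the game watches a calibration pass
#' and takes the maximum progress the player achieves as their personal
#' ROM, which becomes the minimum target to be exceeded while exercising.
#' The result is clamped to \[0.05, 1\] so a failed calibration cannot
#' produce an unreachable (or zero) target.
#'
#' @param samples Numeric vector of progress samples (\[0,1\] or -1), or a
#'   data frame with a `value` column as returned by [track_exercise()].
#' @return A single number in \[0.05, 1\].
#' @section Errors: `handrehab_no_valid_samples` when every sample is a
#'   deviation (-1).
#' @export
measure_initial_rom <- function(samples) {
  if (is.data.frame(samples)) samples <- samples$value
  samples <- as.numeric(samples)
  ok <- samples >= 0
  if (!any(ok))
    hr_stop("no valid (non-deviating) progress samples", "handrehab_no_valid_samples")
  min(1, max(0.05, max(samples[ok])))
}

#' Compute the day's ROM target
#'
#' Version 1 keeps the initially measured ROM as a fixed target
#' (`fixed_initial`). Version 2 recalculates the target daily as the
#' average ROM achieved in the preceding days (`adaptive_daily`): the mean
#' over preceding days of each day's mean peak, optionally restricted to a
#' sliding window of the most recent days. The adaptive target is clamped
#' to \[initial/2, 1\] so one bad day cannot collapse it, and falls back to
#' the initial measurement when no history exists (day 1).
#'
#' @param history List of [rom_record()]s for one exercise (other
#'   exercises' records are ignored). Missing days are simply skipped.
#' @param initial Initially measured ROM in (0, 1].
#' @param day Day the target is computed for (>= 1).
#' @param policy `"fixed_initial"` or `"adaptive_daily"`.
#' @param exercise_id Exercise the target applies to.
#' @param window Number of most recent preceding days entering the
#'   adaptive mean; default `Inf` (all preceding days).
#' @return A `rom_target` with fields `exercise_id`, `day`, `target`,
#'   `policy`.
#' @export
#' @examples
#' h <- list(rom_record("fist", 1, 0.6), rom_record("fist", 2, 0.8))
#' daily_target(h, initial = 0.5, day = 3, policy = "adaptive_daily")$target # 0.7
daily_target <- function(history, initial, day,
                         policy = c("fixed_initial", "adaptive_daily"),
                         exercise_id = NULL, window = Inf) {
  policy <- match.arg(policy)
  stopifnot(is_number(initial), initial > 0, initial <= 1,
            is_number(day), day >= 1)
  if (is.null(exercise_id)) {
    ids <- unique(vapply(history, `[[`, character(1), "exercise_id"))
    exercise_id <- if (length(ids) == 1L) ids else "exercise"
  }
  target <- initial
  if (policy == "adaptive_daily") {
    rel <- Filter(function(r) r$exercise_id == exercise_id && r$day < day,
                  history)
    if (length(rel)) {
      days <- vapply(rel, `[[`, integer(1), "day")
      rel <- rel[days > day - 1 - window]
      if (length(rel)) {
        day_means <- vapply(rel, function(r) mean(r$peaks), numeric(1))
        target <- min(1, max(initial * 0.5, mean(day_means)))
      }
    }
  }
  structure(list(exercise_id = exercise_id, day = as.integer(day),
                 target = target, policy = policy),
            class = "rom_target")
}

#' Traffic-light feedback color for a progress value
#'
#' Direct biofeedback on movement execution: below the target (or while
#' deviating) the hands stay neutral; reaching the target — a recognized
#' repetition — turns them red, and continuing to exceed it moves them
#' through orange to green. The exceedance fraction
#' e = (progress - target) / (1 - target) is cut at thirds:
#' red for e in \[0, 1/3), orange for \[1/3, 2/3), green for e >= 2/3.
#' When the target is already 1, reaching it scores e = 0 (red).
#'
#' @param progress Progress sample in \[0, 1\] or -1.
#' @param target A `rom_target` or bare number in (0, 1].
#' @return A `traffic_light` list with `category` (ordered factor
#'   neutral < red < orange < green) and `exceedance_fraction`.
#' @export
traffic_color <- function(progress, target) {
  tgt <- if (inherits(target, "rom_target")) target$target else target
  stopifnot(is_number(tgt), tgt > 0, tgt <= 1)
  lv <- c("neutral", "red", "orange", "green")
  if (progress < 0 || progress < tgt) {
    cat_ <- "neutral"
    e <- 0
  } else {
    e <- if (tgt >= 1) 0 else (progress - tgt) / (1 - tgt)
    cat_ <- if (e >= 2 / 3) "green" else if (e >= 1 / 3) "orange" else "red"
  }
  structure(list(category = factor(cat_, levels = lv, ordered = TRUE),
                 exceedance_fraction = e),
            class = "traffic_light")
}

#' Score points for a recognized repetition
#'
#' Prototype scoring policy (a documented reconstruction): points scale
#' linearly with the achieved ROM, `round(100 * peak_progress)` per
#' recognized repetition, so a full-range repetition is always worth the
#' maximum 100 points regardless of the exercise.
#'
#' @param event One repetition event (one-row data frame or list with
#'   `peak_progress` and `recognized`).
#' @param target Unused by the prototype policy; accepted for signature
#'   stability.
#' @return Integer points.
#' @export
score_points <- function(event, target = NULL) {
  if (is.data.frame(event)) event <- as.list(event[1L, ])
  if (!isTRUE(event$recognized))
    hr_stop("only recognized repetitions score points", "handrehab_bad_argument")
  as.integer(round(100 * event$peak_progress))
}

#' Per-exercise ROM progression report
#'
#' Chronological summary of achieved ROM per exercise across the training
#' period — the assessment-station view of a player's progress.
#'
#' @param history List of [rom_record()]s.
#' @return Data frame with columns `exercise_id`, `day`, `mean_peak`,
#'   `max_peak`, `n_reps`, ordered by exercise then day. Empty history
#'   gives a zero-row frame.
#' @export
rom_progress_report <- function(history) {
  if (!length(history))
    return(data.frame(exercise_id = character(), day = integer(),
                      mean_peak = numeric(), max_peak = numeric(),
                      n_reps = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(history, function(r)
    data.frame(exercise_id = r$exercise_id, day = r$day,
               mean_peak = mean(r$peaks), max_peak = max(r$peaks),
               n_reps = length(r$peaks), stringsAsFactors = FALSE)))
  df[order(df$exercise_id, df$day), , drop = FALSE]
}
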