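#' Construct a session event
#'
#' Events are the atoms of the in-game time log: the game records all user
#' interactions as timestamped events.
#'
#' @param timestamp Seconds since session start (or absolute).
#' @param kind One of `session_start`, `station_start`, `repetition`,
#'   `station_complete`, `session_end`.
#' @param day Protocol day the event belongs to.
#' @param station_id,exercise_id Optional identifiers.
#' @param duration Repetition duration in seconds (required, > 0, for
#'   `repetition` events).
#' @param peak Peak progress of the repetition.
#' @param recognized Whether the repetition was recognized.
#' @return A one-row data frame (events concatenate with `rbind`).
#' @export
session_event <- function(timestamp, kind, day = NA_integer_,
                          station_id = NA_character_,
                          exercise_id = NA_character_,
                          duration = NA_real_, peak = NA_real_,
                          recognized = NA) {
  kind <- match.arg(kind, c("session_start", "station_start", "repetition",
                            "station_complete", "session_end"))
  if (kind == "repetition" && (!is_number(duration) || duration <= 0))
    hr_stop("repetition events need a positive duration", "handrehab_bad_argument")
  data.frame(timestamp = timestamp, kind = kind, day = as.integer(day),
             station_id = station_id, exercise_id = exercise_id,
             duration = duration, peak = peak, recognized = recognized,
             stringsAsFactors = FALSE)
}

event_columns <- c("timestamp", "kind", "day", "station_id", "exercise_id",
                   "duration", "peak", "recognized")

empty_event_log <- function() {
  session_event(0, "session_start")[0, ]
}

check_event_log <- function(events) {
  stopifnot(is.data.frame(events), all(event_columns %in% names(events)))
  if (nrow(events) > 1L && any(diff(events$timestamp) < 0))
    hr_stop("events must be time-ordered", "handrehab_bad_argument")
  rep_ev <- events$kind == "repetition"
  if (any(rep_ev & !(events$duration > 0)))
    hr_stop("repetition events must carry duration > 0", "handrehab_bad_argument")
  invisible(events)
}

#' Write / parse a session event log
#'
#' Logs are record-per-line text: one JSON object per event per line. The
#' round trip is lossless; parsing reports malformed lines with their line
#' numbers.
#'
#' @param events Event data frame (rows from [session_event()]).
#' @param path File path.
#' @return `parse_log()` returns the event data frame; `write_log()`
#'   returns `path` invisibly.
#' @section Errors: `handrehab_parse_error`, with the offending line number
#'   in the message.
#' @export
write_log <- function(events, path) {
  check_event_log(events)
  lines <- vapply(seq_len(nrow(events)), function(i) {
    rec <- as.list(events[i, event_columns])
    rec <- rec[!vapply(rec, function(x) is.na(x) || is.null(x), logical(1))]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_log
#' @export
parse_log <- function(path) {
  if (!file.exists(path))
    hr_stop(sprintf("log file not found: %s", path), "handrehab_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_event_log())
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) hr_stop(
                      sprintf("malformed event at line %d of %s: %s", i, path,
                              conditionMessage(e)), "handrehab_parse_error"))
    if (is.null(rec$kind) || is.null(rec$timestamp))
      hr_stop(sprintf("event at line %d of %s lacks kind/timestamp", i, path),
              "handrehab_parse_error")
    do.call(session_event, c(
      list(timestamp = rec$timestamp, kind = rec$kind),
      rec[intersect(names(rec), c("day", "station_id", "exercise_id",
                                  "duration", "peak", "recognized"))]))
  })
  out <- do.call(rbind, rows)
  check_event_log(out)
  out
}

# per-subject per-day value -> cohort mean/SE per day
cohort_summarize <- function(per_subject_day, metric) {
  # per_subject_day: data.frame(subject, day, value)
  days <- sort(unique(per_subject_day$day))
  rows <- lapply(days, function(d) {
    v <- per_subject_day$value[per_subject_day$day == d]
    n <- length(v)
    data.frame(day = d, mean = mean(v),
               se = if (n > 1L) stats::sd(v) / sqrt(n) else 0,
               n = n, metric = metric, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Stations completed per day across a cohort
#'
#' Counts `station_complete` events per subject per day, then summarizes
#' across subjects as mean and standard error (SE = sample SD / sqrt(n),
#' n = subjects contributing that day) — the "mean (SE)" convention used
#' for automatically tracked in-game metrics.
#'
#' @param logs Named list of per-subject event data frames (from
#'   [parse_log()] or the simulator).
#' @return A `cohort_summary` data frame: `day`, `mean`, `se`, `n`,
#'   `metric`.
#' @export
stations_per_day <- function(logs) {
  if (!length(logs))
    hr_stop("at least one subject log is required", "handrehab_bad_argument")
  psd <- do.call(rbind, lapply(seq_along(logs), function(s) {
    ev <- logs[[s]]
    days <- sort(unique(ev$day[!is.na(ev$day)]))
    if (!length(days)) return(NULL)
    data.frame(subject = s, day = days,
               value = vapply(days, function(d)
                 sum(ev$kind == "station_complete" & ev$day == d), numeric(1)))
  }))
  cohort_summarize(psd, "stations_per_day")
}

#' Mean repetition duration per day across a cohort
#'
#' Pools each subject's repetition durations per day into a subject-level
#' mean, then reports the cohort mean and SE of those subject means per
#' day. Days on which a subject performed no repetitions do not contribute
#' for that subject.
#'
#' @inheritParams stations_per_day
#' @return A `cohort_summary` data frame (`metric = "rep_duration_s"`).
#' @export
rep_duration_per_day <- function(logs) {
  if (!length(logs))
    hr_stop("at least one subject log is required", "handrehab_bad_argument")
  psd <- do.call(rbind, lapply(seq_along(logs), function(s) {
    ev <- logs[[s]]
    reps <- ev[ev$kind == "repetition" & !is.na(ev$day), , drop = FALSE]
    if (!nrow(reps)) return(NULL)
    agg <- tapply(reps$duration, reps$day, mean)
    data.frame(subject = s, day = as.integer(names(agg)),
               value = as.numeric(agg))
  }))
  if (is.null(psd))
    hr_stop("no repetition events in any log", "handrehab_bad_argument")
  cohort_summarize(psd, "rep_duration_s")
}
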