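#' Define a virtual patient
#'
#' Parameterizes a simulated rehabilitation patient whose range of motion
#' improves day by day with exponential saturation,
#' `rom(day) = rom_limit_0 + (rom_limit_max - rom_limit_0) *
#' (1 - exp(-improvement_rate * (day - 1)))`, and whose repetition
#' durations are log-normally distributed. All randomness is driven by R's
#' default Mersenne-Twister generator through the `seed` field, so streams
#' are reproducible across platforms.
#'
#' Defaults describe a patient with markedly limited initial hand function
#' (60% of the normalized movement range), improving toward near-full
#' range over a 12-session program, taking about 6 s per repetition with
#' moderate variability, under typical optical-tracking jitter.
#'
#' @param rom_limit_0 Initial ROM limit in (0, 1]; default 0.6.
#' @param rom_limit_max Asymptotic ROM limit in (0, 1]; default 0.95.
#' @param improvement_rate Per-day exponential improvement rate (>= 0);
#'   default 0.15.
#' @param rep_duration_mean Mean repetition duration, seconds; default 6.
#' @param rep_duration_cv Coefficient of variation of the log-normal
#'   duration; default 0.2.
#' @param jitter_sd SD of additive per-channel tracking jitter in
#'   normalized feature units; default 0.02.
#' @param deviation_prob Per-repetition probability of an off-path
#'   excursion beyond the deviation tolerance; default 0.05.
#' @param compliance Probability of completing the daily tasks; default 1.
#' @param frame_rate Tracking rate, Hz; default 60 (typical HMD rate).
#' @param seed Integer seed.
#' @return A `virtual_patient` object.
#' @export
virtual_patient <- function(rom_limit_0 = 0.6, rom_limit_max = 0.95,
                            improvement_rate = 0.15,
                            rep_duration_mean = 6, rep_duration_cv = 0.2,
                            jitter_sd = 0.02, deviation_prob = 0.05,
                            compliance = 1, frame_rate = 60, seed = 1L) {
  stopifnot(rom_limit_0 > 0, rom_limit_0 <= rom_limit_max, rom_limit_max <= 1,
            improvement_rate >= 0, rep_duration_mean > 0,
            rep_duration_cv >= 0, jitter_sd >= 0, frame_rate > 0)
  stopifnot_scalar_prob(deviation_prob, "deviation_prob")
  stopifnot_scalar_prob(compliance, "compliance")
  structure(list(rom_limit_0 = rom_limit_0, rom_limit_max = rom_limit_max,
                 improvement_rate = improvement_rate,
                 rep_duration_mean = rep_duration_mean,
                 rep_duration_cv = rep_duration_cv, jitter_sd = jitter_sd,
                 deviation_prob = deviation_prob, compliance = compliance,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "virtual_patient")
}

#' True ROM limit of a patient on a given day
#' @param patient A [virtual_patient()].
#' @param day Protocol day (>= 1).
#' @return ROM limit in (0, 1].
#' @export
rom_on_day <- function(patient, day) {
  patient$rom_limit_0 + (patient$rom_limit_max - patient$rom_limit_0) *
    (1 - exp(-patient$improvement_rate * (day - 1)))
}

# feature vector(s) on the exercise path at parameter(s) p in [0,1]
path_point <- function(exercise, p) {
  P <- keyframe_matrix(exercise)
  K <- nrow(P)
  p <- pmax(pmin(as.numeric(p), 1), 0)   # guard fp noise at the path ends
  seg <- pmax(1L, pmin(K - 1L, floor(p * (K - 1L)) + 1L))
  t <- p * (K - 1L) - (seg - 1L)
  P[seg, , drop = FALSE] * (1 - t) + P[seg + 1L, , drop = FALSE] * t
}

draw_duration <- function(patient, n = 1L) {
  if (patient$rep_duration_cv == 0) return(rep(patient$rep_duration_mean, n))
  sdlog <- sqrt(log(1 + patient$rep_duration_cv^2))
  meanlog <- log(patient$rep_duration_mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)   # mean equals rep_duration_mean
}

# direction off the path at parameter p, unit weighted-RMS norm
offpath_direction <- function(exercise, p) {
  P <- keyframe_matrix(exercise)
  K <- nrow(P)
  seg <- min(K - 1L, floor(p * (K - 1L)) + 1L)
  d <- P[seg + 1L, ] - P[seg, ]
  w <- exercise$channels$weight
  u <- rep_len(c(1, -1), length(d))
  u <- u - sum(w * u * d) / sum(w * d * d) * d   # weighted-orthogonal to path
  n <- sqrt(sum(w * u^2) / sum(w))
  if (n < 1e-9) { u <- seq_along(d) %% 3 - 1; n <- sqrt(sum(w * u^2) / sum(w)) }
  u / n
}

#' Simulate one exercise repetition
#'
#' Sweeps the hand along the exercise's keyframe path from the start
#' position up to the day's ROM limit and back (half-sine progress
#' profile), at the patient's frame rate, with additive Gaussian
#' per-channel jitter. With probability `deviation_prob` the mid-cycle
#' poses are displaced off the path beyond the exercise's deviation
#' tolerance. Uses the current R RNG stream; seed via `set.seed()` or the
#' higher-level simulators.
#'
#' @param patient A [virtual_patient()].
#' @param exercise An [define_exercise()] definition.
#' @param day Protocol day (drives the ROM limit).
#' @param t0 Stream start time, seconds.
#' @param duration Repetition duration; default drawn log-normally.
#' @return A `motion_stream`: list with `timestamps`, `features` (matrix),
#'   `channels`, and `truth` (`start`, `end`, `peak` = the day's ROM
#'   limit, `deviated`).
#' @export
simulate_repetition <- function(patient, exercise, day = 1, t0 = 0,
                                duration = NULL) {
  rom <- rom_on_day(patient, day)
  if (is.null(duration)) duration <- draw_duration(patient)
  n <- max(4L, round(duration * patient$frame_rate))
  tt <- t0 + duration * seq_len(n) / n
  p <- rom * sin(pi * seq_len(n) / n)
  X <- path_point(exercise, p)
  deviated <- stats::runif(1) < patient$deviation_prob
  if (deviated) {
    # off-path through the middle half of the cycle, covering the peak, so a
    # deviated repetition cannot reach its target while on the path
    mid <- seq_len(n) > 0.3 * n & seq_len(n) < 0.8 * n
    u <- offpath_direction(exercise, rom * 0.95)
    X[mid, ] <- X[mid, , drop = FALSE] +
      matrix(2 * exercise$deviation_tolerance * u, sum(mid), ncol(X),
             byrow = TRUE)
  }
  if (patient$jitter_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, patient$jitter_sd),
                    nrow(X), ncol(X))
  X <- pmax(pmin(X, 1), 0)   # first arg keeps the matrix dim
  colnames(X) <- exercise$channels$channel
  structure(list(timestamps = tt, features = X, channels = exercise$channels,
                 truth = list(start = t0, end = t0 + duration, peak = rom,
                              deviated = deviated)),
            class = "motion_stream")
}

#' Simulate a run of consecutive repetitions
#'
#' Concatenates `n_reps` repetitions of one exercise into a single
#' contiguous stream with per-repetition ground-truth intervals.
#'
#' @inheritParams simulate_repetition
#' @param n_reps Number of repetitions.
#' @return A `motion_stream` whose `truth` is a data frame with one row per
#'   repetition (`start`, `end`, `duration`, `peak`, `deviated`).
#' @export
simulate_exercise_run <- function(patient, exercise, day = 1, n_reps = 10L,
                                  t0 = 0) {
  parts <- vector("list", n_reps)
  t <- t0
  for (i in seq_len(n_reps)) {
    parts[[i]] <- simulate_repetition(patient, exercise, day, t0 = t)
    t <- parts[[i]]$truth$end
  }
  truth <- do.call(rbind, lapply(parts, function(s)
    data.frame(start = s$truth$start, end = s$truth$end,
               duration = s$truth$end - s$truth$start,
               peak = s$truth$peak, deviated = s$truth$deviated)))
  structure(list(timestamps = do.call(c, lapply(parts, `[[`, "timestamps")),
                 features = do.call(rbind, lapply(parts, `[[`, "features")),
                 channels = exercise$channels, truth = truth),
            class = "motion_stream")
}

#' Materialize a motion stream as tracked frames
#'
#' Converts a feature-space `motion_stream` into a list of
#' [tracked_frame()]s with full [hand_pose()] objects (the inverse feature
#' map), as an optical tracking source would deliver them.
#'
#' @param stream A `motion_stream`.
#' @param side Hand to populate.
#' @param view_direction View direction stored on every frame.
#' @return List of `tracked_frame`s.
#' @export
stream_frames <- function(stream, side = "right", view_direction = c(0, 0, 1)) {
  wf <- if (any(stream$channels$channel %in% wrist_channels()))
    compute_wrist_frame(view_direction) else NULL
  lapply(seq_along(stream$timestamps), function(i) {
    pose <- features_to_pose(stream$features[i, ], stream$channels,
                             side = side, frame = wf)
    tracked_frame(stream$timestamps[i],
                  left = if (side == "left") pose,
                  right = if (side == "right") pose,
                  view_direction = view_direction)
  })
}

#' Simulate one protocol session
#'
#' Plays one day of the protocol for a virtual patient: with probability
#' `compliance` the day's 2 mandatory stations are completed in full (6
#' exercises x 10 recognized repetitions each); otherwise only half of
#' each quota is performed and no station completes. Repetitions are
#' registered with the protocol state and emitted as a session event log
#' in the same format the analytics module parses. Ground-truth repetition
#' intervals come from the generator itself.
#'
#' @param patient A [virtual_patient()].
#' @param state A [game_state()] positioned at the day to play.
#' @param library Exercise library indexed by id (defaults to the builtin
#'   library of the state's variant).
#' @param include_streams If `TRUE`, also return the per-exercise
#'   `motion_stream`s (memory-heavy; off by default).
#' @return List with `state` (repetitions registered; day not yet
#'   advanced), `events` (event log data frame), `truth` (per-repetition
#'   ground truth with station/exercise ids), and optionally `streams`.
#' @export
simulate_session <- function(patient, state, library = NULL,
                             include_streams = FALSE) {
  if (is.null(library))
    library <- builtin_library(if (state$variant == "prototype") "prototype" else "v1")
  lib_ids <- vapply(library, `[[`, character(1), "id")
  plan <- day_plan(state)
  day <- plan$day
  comply <- stats::runif(1) < patient$compliance ||
    patient$compliance >= 1    # degenerate prob 1 must never fail
  events <- list(session_event(0, "session_start", day = day))
  truth <- list()
  streams <- list()
  t <- 0
  for (sid in plan$mandatory_tasks) {
    st <- state$stations[[sid]]
    t <- t + 1
    events[[length(events) + 1L]] <- session_event(t, "station_start",
                                                   day = day, station_id = sid)
    for (ex_id in st$exercise_ids) {
      ex <- library[[match(ex_id, lib_ids)]]
      n_reps <- if (comply) st$reps_per_exercise
                else max(1L, st$reps_per_exercise %/% 2L)
      run <- simulate_exercise_run(patient, ex, day, n_reps = n_reps, t0 = t)
      if (include_streams) streams[[paste(sid, ex_id, sep = "/")]] <- run
      for (i in seq_len(nrow(run$truth))) {
        rep_i <- run$truth[i, ]
        evt <- session_event(rep_i$end, "repetition", day = day,
                             station_id = sid, exercise_id = ex_id,
                             duration = rep_i$duration,
                             peak = rep_i$peak,
                             recognized = !rep_i$deviated)
        events[[length(events) + 1L]] <- evt
        state <- register_repetition(state, sid, ex_id, evt)
      }
      # deviated repetitions are redone until the quota is met (bounded)
      redo <- 0L
      while (comply && state$reps[[sid]][ex_id] < st$reps_per_exercise &&
             redo < 10L * st$reps_per_exercise) {
        redo <- redo + 1L
        extra <- simulate_repetition(patient, ex, day,
                                     t0 = max(run$truth$end))
        run$truth <- rbind(run$truth,
                           data.frame(start = extra$truth$start,
                                      end = extra$truth$end,
                                      duration = extra$truth$end - extra$truth$start,
                                      peak = extra$truth$peak,
                                      deviated = extra$truth$deviated))
        evt <- session_event(extra$truth$end, "repetition", day = day,
                             station_id = sid, exercise_id = ex_id,
                             duration = extra$truth$end - extra$truth$start,
                             peak = extra$truth$peak,
                             recognized = !extra$truth$deviated)
        events[[length(events) + 1L]] <- evt
        state <- register_repetition(state, sid, ex_id, evt)
      }
      truth[[paste(sid, ex_id, sep = "/")]] <-
        cbind(station_id = sid, exercise_id = ex_id, run$truth,
              stringsAsFactors = FALSE)
      t <- max(c(t, run$truth$end)) + 0.5
    }
    if (station_complete(state, sid))
      events[[length(events) + 1L]] <- session_event(t, "station_complete",
                                                     day = day,
                                                     station_id = sid)
  }
  events[[length(events) + 1L]] <- session_event(t + 1, "session_end",
                                                 day = day)
  out <- list(state = state, events = do.call(rbind, events),
              truth = do.call(rbind, truth))
  rownames(out$truth) <- NULL
  if (include_streams) out$streams <- streams
  out
}

#' Simulate a cohort trial
#'
#' Runs `n_subjects` virtual patients through the full protocol,
#' heterogeneous parameters drawn uniformly from `param_ranges`,
#' deterministic for a fixed `seed`. Each subject's per-day sessions are
#' simulated, registered with the protocol scheduler and logged.
#'
#' @param n_subjects Cohort size; default 10.
#' @param variant Protocol variant; default `"v1"`.
#' @param days Number of sessions; default the protocol length.
#' @param seed Integer master seed.
#' @param param_ranges Named list of length-2 numeric ranges for
#'   `rom_limit_0`, `rom_limit_max`, `improvement_rate`,
#'   `rep_duration_mean`; degenerate ranges (equal endpoints) pin a
#'   parameter.
#' @param ... Remaining [virtual_patient()] fields shared by the cohort
#'   (e.g. `jitter_sd`, `deviation_prob`, `compliance`).
#' @return A `cohort_trial`: list with `subjects` (each holding `patient`,
#'   `log`, `truth`, `final_state`, `unlocked`) and `logs` (the per-subject
#'   event logs, ready for the analytics functions).
#' @export
simulate_trial <- function(n_subjects = 10L, variant = "v1", days = NULL,
                           seed = 1L,
                           param_ranges = list(
                             rom_limit_0 = c(0.5, 0.7),
                             rom_limit_max = c(0.9, 1.0),
                             improvement_rate = c(0.1, 0.3),
                             rep_duration_mean = c(5, 7)),
                           ...) {
  if (is.null(days)) days <- protocol_length(variant)
  set.seed(seed)
  draws <- lapply(param_ranges, function(r)
    stats::runif(n_subjects, r[1], r[2]))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(seed + 7919L * s)
    patient <- virtual_patient(
      rom_limit_0 = draws$rom_limit_0[s],
      rom_limit_max = draws$rom_limit_max[s],
      improvement_rate = draws$improvement_rate[s],
      rep_duration_mean = draws$rep_duration_mean[s],
      seed = seed + 7919L * s, ...)
    state <- game_state(variant, seed = seed + s)
    log <- list()
    truth <- list()
    for (d in seq_len(min(days, protocol_length(variant)))) {
      ses <- simulate_session(patient, state)
      state <- advance_day(ses$state)
      # session clocks are session-relative; anchor each day at a daily
      # epoch so a subject's multi-day log is globally time-ordered
      ses$events$timestamp <- ses$events$timestamp + (d - 1) * 86400
      log[[d]] <- ses$events
      truth[[d]] <- ses$truth
    }
    subjects[[s]] <- list(patient = patient,
                          log = do.call(rbind, log),
                          truth = do.call(rbind, truth),
                          final_state = state,
                          unlocked = length(state$unlocked))
  }
  structure(list(subjects = subjects,
                 logs = lapply(subjects, `[[`, "log"),
                 seed = seed, variant = variant, days = days),
            class = "cohort_trial")
}
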