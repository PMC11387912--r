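#' Station plan: 6 exercises, 10 repetitions each
#'
#' Each farm station bundles a themed task whose completion is divided
#' into 6 exercises, each repeated 10 times — 60 recognized repetitions
#' per station.
#'
#' @param station_id Identifier.
#' @param exercise_ids Character vector of exactly 6 exercise ids.
#' @param reps_per_exercise Positive rep quota per exercise; default 10.
#' @return A `station_plan` object.
#' @export
station_plan <- function(station_id, exercise_ids, reps_per_exercise = 10L) {
  if (length(exercise_ids) != 6L)
    hr_stop("a station comprises exactly 6 exercises", "handrehab_bad_argument")
  if (!is_number(reps_per_exercise) || reps_per_exercise < 1)
    hr_stop("reps_per_exercise must be positive", "handrehab_bad_argument")
  structure(list(station_id = as.character(station_id),
                 exercise_ids = as.character(exercise_ids),
                 reps_per_exercise = as.integer(reps_per_exercise)),
            class = "station_plan")
}

protocol_length <- function(variant) {
  if (variant == "prototype") 4L else 12L
}

#' Exercise-introduction days of the 12-session protocol
#' @return Integer vector: days on which new exercises are introduced.
#' @export
introduction_days <- function() c(1L, 4L, 7L, 10L)

#' Initialize the game protocol state
#'
#' Builds the full protocol state for one player: the station roster (12
#' stations for v1/v2, 3 for the prototype), each station's 6-exercise
#' assignment drawn from the library (cycled, restricted to exercises whose
#' introduction day permits them by the time a station can be in play), the
#' initially unlocked set, and empty rep/quota bookkeeping.
#'
#' The initially unlocked set has 2 stations — the minimum that supports 2
#' mandatory daily tasks on day 1. The station-to-exercise mapping is a
#' deterministic fixture derived from the library order and the seed.
#'
#' @param variant `"prototype"`, `"v1"` or `"v2"`. The prototype runs 4
#'   sessions over 3 stations with a fixed unlock schedule; v1 and v2 run
#'   12 sessions over 12 stations unlocked one per day after the daily
#'   tasks are fulfilled (v2 inherits the v1 schedule).
#' @param library Exercise library; default [builtin_library()] matching
#'   the variant.
#' @param seed Integer seed driving the round-robin task rotation.
#' @return A `game_state` object.
#' @export
game_state <- function(variant = c("v1", "v2", "prototype"), library = NULL,
                       seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(library))
    library <- builtin_library(if (variant == "prototype") "prototype" else "v1")
  n_st <- if (variant == "prototype") 3L else 12L
  ex_ids <- vapply(library, `[[`, character(1), "id")
  intro <- vapply(library, `[[`, integer(1), "introduced_on_day")
  # day-1 exercises fill the roster; later introductions rotate in via day_plan
  base_ids <- ex_ids[intro == 1L]
  if (length(base_ids) < 6L)
    hr_stop("library must hold at least 6 day-1 exercises", "handrehab_bad_argument")
  stations <- lapply(seq_len(n_st), function(i) {
    sel <- base_ids[((i - 1L) * 2L + seq_len(6L) - 1L) %% length(base_ids) + 1L]
    station_plan(sprintf("station_%02d", i), sel)
  })
  names(stations) <- vapply(stations, `[[`, character(1), "station_id")
  quotas <- lapply(stations, function(s)
    setNames(integer(length(s$exercise_ids)), s$exercise_ids))
  structure(list(
    variant = variant, day = 1L, seed = as.integer(seed),
    stations = stations,
    exercise_intro = setNames(intro, ex_ids),
    unlocked = names(stations)[1:2],
    reps = quotas,                       # recognized reps per station/exercise
    completed = setNames(vector("list", 0L), character()),  # day -> station ids
    tasks_done = logical(0),             # per day, filled by register/advance
    current_tasks = character(0),
    finished = FALSE
  ), class = "game_state")
}

#' Plan one protocol day
#'
#' Assigns the day's 2 mandatory station tasks (round-robin over the
#' unlocked stations, rotation offset by the state's seed so assignments
#' vary deterministically across days), and lists the exercises newly
#' introduced that day. Completing the mandatory tasks gives access to all
#' other unlocked stations and earns the daily station unlock.
#'
#' @param state A [game_state()].
#' @return A `day_plan` with `day`, `mandatory_tasks` (2 station ids),
#'   `unlocked_stations`, `newly_introduced_exercises`.
#' @section Errors: `handrehab_protocol_exhausted` past the protocol's last
#'   day (4 sessions for the prototype, 12 for v1/v2).
#' @export
day_plan <- function(state) {
  stopifnot(inherits(state, "game_state"))
  if (state$day > protocol_length(state$variant))
    hr_stop(sprintf("protocol exhausted: day %d beyond the %d-session %s protocol",
                    state$day, protocol_length(state$variant), state$variant),
            "handrehab_protocol_exhausted")
  un <- state$unlocked
  off <- (state$seed + (state$day - 1L) * 2L) %% length(un)
  tasks <- un[(off + seq_len(2L) - 1L) %% length(un) + 1L]
  if (tasks[1] == tasks[2]) tasks[2] <- un[(off + 1L) %% length(un) + 1L]
  intro_days <- if (state$variant == "prototype") 1L else introduction_days()
  new_ex <- if (state$day %in% intro_days)
    names(state$exercise_intro)[state$exercise_intro == state$day]
  else character(0)
  structure(list(day = state$day, mandatory_tasks = tasks,
                 unlocked_stations = un,
                 newly_introduced_exercises = new_ex),
            class = "day_plan")
}

#' Register a repetition with the protocol bookkeeping
#'
#' Only recognized repetitions advance the station quotas. A station
#' becomes complete exactly when all 6 of its exercises reach their 10-rep
#' quota; completing both of the day's mandatory stations fulfills the
#' daily tasks (which [advance_day()] rewards with a new station).
#'
#' @param state A [game_state()] (with the current [day_plan()] applied).
#' @param station_id Station the repetition was performed at.
#' @param exercise_id Exercise that was repeated.
#' @param event Repetition event (from the tracker); only
#'   `recognized == TRUE` events count.
#' @return The updated `game_state`.
#' @section Errors: `handrehab_locked_station` when the station is not yet
#'   unlocked.
#' @export
register_repetition <- function(state, station_id, exercise_id, event) {
  if (!station_id %in% state$unlocked)
    hr_stop(sprintf("station %s is locked", station_id),
            "handrehab_locked_station")
  if (is.data.frame(event)) event <- as.list(event[1L, ])
  if (!isTRUE(event$recognized)) return(state)
  st <- state$stations[[station_id]]
  if (!exercise_id %in% st$exercise_ids)
    hr_stop(sprintf("exercise %s is not part of station %s", exercise_id,
                    station_id), "handrehab_bad_argument")
  quota <- st$reps_per_exercise
  cnt <- state$reps[[station_id]][exercise_id]
  if (cnt >= quota) return(state)        # quota already met; no extra credit
  state$reps[[station_id]][exercise_id] <- cnt + 1L
  if (all(state$reps[[station_id]] >= quota)) {
    key <- as.character(state$day)
    done <- state$completed[[key]]
    if (!station_id %in% done)
      state$completed[[key]] <- c(done, station_id)
  }
  state
}

#' Is a station complete (all 6 exercises at quota)?
#' @param state A [game_state()].
#' @param station_id Station to check.
#' @return Logical.
#' @export
station_complete <- function(state, station_id) {
  st <- state$stations[[station_id]]
  all(state$reps[[station_id]] >= st$reps_per_exercise)
}

tasks_fulfilled <- function(state, plan) {
  all(vapply(plan$mandatory_tasks, station_complete, logical(1),
             state = state))
}

#' Close the day: apply the unlock reward and advance the day counter
#'
#' For v1/v2, fulfilling the day's 2 mandatory tasks is rewarded with one
#' additional station, until all 12 stations are revealed; unfulfilled
#' tasks leave the unlock set unchanged. The prototype instead follows its
#' fixed schedule: a third station is unlocked stepwise over the first 3
#' days and becomes playable on day 4. Station rep counters reset for the
#' new day (each day's station runs start fresh).
#'
#' @param state A [game_state()].
#' @param plan The day's [day_plan()]; defaults to `day_plan(state)`.
#' @return The updated `game_state` with `day` incremented.
#' @export
advance_day <- function(state, plan = NULL) {
  if (is.null(plan)) plan <- day_plan(state)
  stopifnot(plan$day == state$day)
  fulfilled <- tasks_fulfilled(state, plan)
  state$tasks_done <- c(state$tasks_done, fulfilled)
  all_ids <- names(state$stations)
  locked <- setdiff(all_ids, state$unlocked)
  if (state$variant == "prototype") {
    # third station unlocks across days 1-3, playable on day 4
    if (state$day == 3L && length(locked)) state$unlocked <- c(state$unlocked, locked[1])
  } else if (fulfilled && length(locked)) {
    state$unlocked <- c(state$unlocked, locked[1])
  }
  for (sid in names(state$reps)) state$reps[[sid]][] <- 0L
  state$day <- state$day + 1L
  if (state$day > protocol_length(state$variant)) state$finished <- TRUE
  state
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("<game_state> %s, day %d/%d, %d/%d stations unlocked\n",
              x$variant, min(x$day, protocol_length(x$variant)),
              protocol_length(x$variant), length(x$unlocked),
              length(x$stations)))
  invisible(x)
}
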