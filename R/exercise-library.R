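#' Pose keyframe
#'
#' A stored hand position (start, middle or end of a movement) in
#' normalized feature space.
#'
#' @param label `"start"`, `"middle"` or `"end"`.
#' @param features Named numeric vector in \[0, 1\] per channel.
#' @param source_pose Optional [hand_pose()] snapshot the keyframe was
#'   recorded from.
#' @return A `pose_keyframe` object.
#' @export
pose_keyframe <- function(label, features, source_pose = NULL) {
  label <- match.arg(label, c("start", "middle", "end"))
  if (any(!is.finite(features)) || any(features < -1e-9) || any(features > 1 + 1e-9))
    hr_stop("keyframe features must lie in [0, 1]", "handrehab_bad_keyframe")
  if (is.null(names(features)) || anyDuplicated(names(features)))
    hr_stop("keyframe features must have unique channel names",
            "handrehab_bad_keyframe")
  feat <- pmax(pmin(features, 1), 0)   # keeps names (first arg wins)
  structure(list(label = label, features = feat, source_pose = source_pose),
            class = "pose_keyframe")
}

#' Record a keyframe from a stable window of a motion stream
#'
#' Takes the per-channel median over the window, which is robust to
#' tracking jitter while the hand is held still. If the hand was moving —
#' per-channel spread (interquartile range) above `spread_threshold` — the
#' window is rejected.
#'
#' @param stream A list of [tracked_frame()]s, or a numeric matrix of
#'   feature vectors (rows = frames, columns = channels).
#' @param channels A [channel_spec()]; required when `stream` is a list of
#'   frames.
#' @param side Which hand to read from tracked frames.
#' @param label Keyframe label.
#' @param min_frames Minimum number of valid frames in the window.
#' @param spread_threshold Maximum tolerated per-channel IQR in feature
#'   units; default 0.1.
#' @return A [pose_keyframe()].
#' @section Errors: `handrehab_unstable_window` when any channel's spread
#'   exceeds the threshold; `handrehab_bad_argument` when fewer than
#'   `min_frames` valid frames are supplied.
#' @export
record_keyframe <- function(stream, channels = NULL, side = "right",
                            label = "start", min_frames = 5L,
                            spread_threshold = 0.1) {
  X <- stream_features(stream, channels, side)
  if (nrow(X) < min_frames)
    hr_stop(sprintf("keyframe window needs >= %d valid frames, got %d",
                    min_frames, nrow(X)), "handrehab_bad_argument")
  spread <- apply(X, 2L, stats::IQR)
  if (any(spread > spread_threshold))
    hr_stop(sprintf(
      "hand was moving during the window: channel spread up to %.3f exceeds %.3f",
      max(spread), spread_threshold), "handrehab_unstable_window")
  pose_keyframe(label, apply(X, 2L, stats::median))
}

# coerce a stream (frame list or feature matrix) to a feature matrix
stream_features <- function(stream, channels = NULL, side = "right",
                            frame = NULL) {
  if (is.matrix(stream)) return(stream)
  if (inherits(stream, "motion_stream")) return(stream$features)
  if (!is.list(stream) || !length(stream))
    hr_stop("stream must be a non-empty frame list or feature matrix",
            "handrehab_bad_argument")
  if (is.null(channels))
    hr_stop("channels required to extract features from tracked frames",
            "handrehab_bad_argument")
  keep <- vapply(stream, function(fr) !is.null(fr[[side]]), logical(1))
  rows <- lapply(stream[keep], function(fr) {
    fra <- frame
    if (is.null(fra) && any(channels$channel %in% wrist_channels()))
      fra <- compute_wrist_frame(fr$view_direction)
    pose_to_features(fr[[side]], channels, fra)
  })
  do.call(rbind, rows)
}

#' Define an exercise movement from keyframes
#'
#' An exercise is an ordered path through feature space: a start position,
#' optional middle positions (one middle gives the more accurate 3-point
#' mapping), and an end position. Progress along the path is the movement's
#' normalized range-of-motion coordinate.
#'
#' @param id,name Identifier and display name.
#' @param start,end [pose_keyframe()]s (labels are overridden).
#' @param middles List of middle [pose_keyframe()]s, possibly empty.
#' @param channels A [channel_spec()] shared by all keyframes.
#' @param bilateral_mode `"single"`, `"synchronous"` or `"opposite"`.
#' @param deviation_tolerance Feature-space distance beyond which a hand
#'   position counts as deviating from the movement (progress -1).
#'   Default 0.25.
#' @param min_step Minimum feature distance between consecutive keyframes
#'   so the path has positive length; default 0.05.
#' @param introduced_on_day Protocol day on which the exercise first
#'   appears (1, 4, 7 or 10 in the 12-session protocol).
#' @param demo_repetitions Metadata only: number of complete repetitions the
#'   in-game preview hands demonstrate before disappearing (default 2).
#' @return An `exercise_definition`.
#' @section Errors: `handrehab_degenerate_path` when consecutive keyframes
#'   are closer than `min_step`.
#' @export
#' @examples
#' ch <- channel_spec()
#' open <- pose_keyframe("start", setNames(rep(0, 15), ch$channel))
#' fist <- pose_keyframe("end", setNames(rep(1, 15), ch$channel))
#' define_exercise("fist", "Close the fist", open, fist, channels = ch)
define_exercise <- function(id, name, start, end, middles = list(),
                            channels = channel_spec(),
                            bilateral_mode = c("single", "synchronous", "opposite"),
                            deviation_tolerance = 0.25, min_step = 0.05,
                            introduced_on_day = 1L, demo_repetitions = 2L) {
  bilateral_mode <- match.arg(bilateral_mode)
  stopifnot(is_channel_spec(channels), inherits(start, "pose_keyframe"),
            inherits(end, "pose_keyframe"))
  if (!is_number(deviation_tolerance) || deviation_tolerance <= 0)
    hr_stop("deviation_tolerance must be positive", "handrehab_bad_argument")
  if (!is_number(introduced_on_day) || introduced_on_day < 1)
    hr_stop("introduced_on_day must be a positive integer", "handrehab_bad_argument")
  kfs <- c(list(start), middles, list(end))
  kfs[[1]]$label <- "start"
  if (length(kfs) > 2L)
    for (i in 2:(length(kfs) - 1L)) kfs[[i]]$label <- "middle"
  kfs[[length(kfs)]]$label <- "end"
  for (k in kfs) {
    if (!inherits(k, "pose_keyframe"))
      hr_stop("all keyframes must be pose_keyframe objects", "handrehab_bad_argument")
    if (!identical(names(k$features), channels$channel))
      hr_stop("keyframe channels do not match the exercise channel spec",
              "handrehab_channel_mismatch")
  }
  P <- do.call(rbind, lapply(kfs, `[[`, "features"))
  w <- channels$weight
  for (i in seq_len(nrow(P) - 1L)) {
    d <- feature_dist(P[i, ], P[i + 1L, ], w)
    if (d < min_step)
      hr_stop(sprintf(
        "degenerate path: keyframes %d and %d are %.4f apart (min %.3f)",
        i, i + 1L, d, min_step), "handrehab_degenerate_path")
  }
  structure(list(id = as.character(id), name = as.character(name),
                 keyframes = kfs, channels = channels,
                 bilateral_mode = bilateral_mode,
                 deviation_tolerance = deviation_tolerance,
                 min_step = min_step,
                 introduced_on_day = as.integer(introduced_on_day),
                 demo_repetitions = as.integer(demo_repetitions)),
            class = "exercise_definition")
}

#' @export
print.exercise_definition <- function(x, ...) {
  cat(sprintf("<exercise_definition> %s (\"%s\"): %d keyframes, %s, day %d\n",
              x$id, x$name, length(x$keyframes), x$bilateral_mode,
              x$introduced_on_day))
  invisible(x)
}

# keyframe matrix (K x C) of an exercise
keyframe_matrix <- function(exercise) {
  do.call(rbind, lapply(exercise$keyframes, `[[`, "features"))
}

# --- builtin libraries ----------------------------------------------------

# Feature-space pose sketches used to synthesize the builtin movements.
# These are plausible named placeholders with the documented structure
# (basic open/close movements, wrist rotations, compound and bilateral
# variants), not clinically validated exercise content.
builtin_pose <- function(what, channels) {
  f <- setNames(rep(0, nrow(channels)), channels$channel)
  finger <- function(fingers, joints = c("mcp", "pip", "dip"), v = 1)
    unlist(lapply(fingers, function(fg) setNames(rep(v, length(joints)),
                                                 paste(fg, joints, sep = "_"))))
  set <- function(x, v) { f[names(v)[names(v) %in% names(f)]] <<- v[names(v) %in% names(f)] }
  longs <- c("index", "middle", "ring", "little")
  switch(what,
    open = NULL,
    fist = set(f, c(thumb_cmc = 0.5, thumb_mcp = 0.8, thumb_ip = 0.8,
                    finger(longs, v = 1))),
    half_fist = set(f, c(thumb_cmc = 0.25, thumb_mcp = 0.4, thumb_ip = 0.4,
                         finger(longs, v = 0.5))),
    hook = set(f, finger(longs, c("pip", "dip"), 1)),
    tabletop = set(f, finger(longs, "mcp", 1)),
    book_grip = set(f, c(thumb_cmc = 0.4, thumb_mcp = 0.3, thumb_ip = 0.2,
                         finger(longs, v = 0.45))),
    pinch_index = set(f, c(thumb_cmc = 0.6, thumb_mcp = 0.5, thumb_ip = 0.5,
                           finger("index", v = 0.7))),
    pinch_little = set(f, c(thumb_cmc = 0.8, thumb_mcp = 0.6, thumb_ip = 0.6,
                            finger("little", v = 0.8))),
    thumb_sweep = set(f, c(thumb_cmc = 1, thumb_mcp = 0.7, thumb_ip = 0.5)),
    claw = set(f, c(thumb_mcp = 0.6, thumb_ip = 0.9,
                    finger(longs, c("pip", "dip"), 0.9),
                    finger(longs, "mcp", 0.15))),
    pron_neutral = set(f, c(wrist_pronation = 0.5, wrist_flexion = 0.5,
                            wrist_deviation = 0.5)),
    pron_full = set(f, c(wrist_pronation = 1, wrist_flexion = 0.5,
                         wrist_deviation = 0.5)),
    wrist_flex = set(f, c(wrist_pronation = 0.5, wrist_flexion = 1,
                          wrist_deviation = 0.5)),
    wrist_dev = set(f, c(wrist_pronation = 0.5, wrist_flexion = 0.5,
                         wrist_deviation = 0.85)),
    fist_pron = set(f, c(thumb_cmc = 0.5, thumb_mcp = 0.8, thumb_ip = 0.8,
                         finger(longs, v = 1), wrist_pronation = 1,
                         wrist_flexion = 0.5, wrist_deviation = 0.5)),
    hook_flex = set(f, c(finger(longs, c("pip", "dip"), 1),
                         wrist_pronation = 0.5, wrist_flexion = 0.9,
                         wrist_deviation = 0.5)),
    stop("unknown builtin pose: ", what)
  )
  f
}

builtin_def <- function(id, name, from, to, channels, mode = "single",
                        day = 1L) {
  define_exercise(
    id, name,
    start = pose_keyframe("start", builtin_pose(from, channels)),
    end = pose_keyframe("end", builtin_pose(to, channels)),
    channels = channels, bilateral_mode = mode, introduced_on_day = day)
}

#' Builtin exercise libraries
#'
#' The prototype library holds the 6 basic hand movements; the version-1
#' library expands it to 17 movements introduced on protocol days 1, 4, 7
#' and 10, including compound movements (e.g. closing the fist while
#' pronating the wrist) and bilateral synchronous/opposite variants.
#'
#' The concrete movement list is a synthesized placeholder set with this
#' documented structure — named fixtures, not clinical content.
#'
#' @param version `"prototype"` (6 exercises) or `"v1"` (17 movements).
#' @return List of [define_exercise()] definitions, each validated.
#' @export
#' @examples
#' length(builtin_library("prototype"))  # 6
#' length(builtin_library("v1"))         # 17
builtin_library <- function(version = c("prototype", "v1")) {
  version <- match.arg(version)
  ch <- channel_spec()                    # joint channels only
  chw <- channel_spec(wrist = TRUE)       # joints + wrist rotations
  basics <- list(
    builtin_def("fist", "Close the hand into a fist", "open", "fist", ch),
    builtin_def("hook", "Hook fist", "open", "hook", ch),
    builtin_def("tabletop", "Table-top position", "open", "tabletop", ch),
    builtin_def("book_grip", "Grip for holding a book", "open", "book_grip", ch),
    builtin_def("thumb_sweep", "Sweep the thumb across the palm", "open",
                "thumb_sweep", ch),
    builtin_def("pronation", "Pronate the forearm", "pron_neutral",
                "pron_full", chw)
  )
  if (version == "prototype") return(basics)
  day4 <- list(
    builtin_def("pinch_index", "Pinch thumb to index finger", "open",
                "pinch_index", ch, day = 4L),
    builtin_def("pinch_little", "Pinch thumb to little finger", "open",
                "pinch_little", ch, day = 4L),
    builtin_def("wrist_flexion", "Flex the wrist", "pron_neutral",
                "wrist_flex", chw, day = 4L),
    builtin_def("wrist_deviation", "Radial-ulnar wrist deviation",
                "pron_neutral", "wrist_dev", chw, day = 4L)
  )
  day7 <- list(
    builtin_def("fist_pronation", "Close the fist while pronating the wrist",
                "pron_neutral", "fist_pron", chw, day = 7L),
    builtin_def("hook_wrist_flex", "Hook fist with wrist flexion",
                "pron_neutral", "hook_flex", chw, day = 7L),
    builtin_def("claw", "Claw position", "open", "claw", ch, day = 7L),
    builtin_def("half_to_full_fist", "Half fist to full fist", "half_fist",
                "fist", ch, day = 7L)
  )
  day10 <- list(
    builtin_def("fist_sync", "Close both fists in synchrony", "open", "fist",
                ch, mode = "synchronous", day = 10L),
    builtin_def("fist_opposite", "Alternate fists in opposite directions",
                "open", "fist", ch, mode = "opposite", day = 10L),
    builtin_def("tabletop_sync", "Table-top with both hands", "open",
                "tabletop", ch, mode = "synchronous", day = 10L)
  )
  c(basics, day4, day7, day10)
}

# --- persistence ----------------------------------------------------------

library_schema <- "handrehab-library/1"

kf_to_record <- function(k) list(label = k$label, features = as.list(k$features))

record_to_kf <- function(r) {
  pose_keyframe(r$label, unlist(r$features))
}

#' Save / load an exercise library
#'
#' Libraries are persisted as a single schema-versioned JSON document;
#' the round trip is lossless (features at full double precision).
#'
#' @param library List of `exercise_definition`s.
#' @param path File path.
#' @return `load_library()` returns the list of definitions;
#'   `save_library()` returns `path` invisibly.
#' @section Errors: `handrehab_schema_mismatch` for a different schema
#'   version; `handrehab_parse_error` for malformed or empty files.
#' @export
save_library <- function(library, path) {
  stopifnot(all(vapply(library, inherits, logical(1), "exercise_definition")))
  doc <- list(
    schema = library_schema,
    exercises = lapply(library, function(ex) list(
      id = ex$id, name = ex$name,
      bilateral_mode = ex$bilateral_mode,
      deviation_tolerance = ex$deviation_tolerance,
      min_step = ex$min_step,
      introduced_on_day = ex$introduced_on_day,
      demo_repetitions = ex$demo_repetitions,
      channels = lapply(seq_len(nrow(ex$channels)), function(i)
        as.list(ex$channels[i, c("channel", "weight", "lo", "hi")])),
      keyframes = lapply(ex$keyframes, kf_to_record)
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    hr_stop(sprintf("library file missing or empty: %s", path),
            "handrehab_parse_error")
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) hr_stop(
                    sprintf("malformed library file %s: %s", path,
                            conditionMessage(e)), "handrehab_parse_error"))
  if (!identical(doc$schema, library_schema))
    hr_stop(sprintf("library schema '%s' does not match expected '%s'",
                    if (is.null(doc$schema)) "<none>" else doc$schema,
                    library_schema), "handrehab_schema_mismatch")
  lapply(doc$exercises, function(r) {
    chdf <- do.call(rbind, lapply(r$channels, function(cc)
      data.frame(channel = cc$channel, weight = cc$weight, lo = cc$lo,
                 hi = cc$hi, stringsAsFactors = FALSE)))
    class(chdf) <- c("channel_spec", "data.frame")
    kfs <- lapply(r$keyframes, function(k) {
      f <- unlist(k$features)
      pose_keyframe(k$label, setNames(as.numeric(f), names(f)))
    })
    define_exercise(r$id, r$name, start = kfs[[1]],
                    end = kfs[[length(kfs)]],
                    middles = if (length(kfs) > 2L) kfs[2:(length(kfs) - 1L)] else list(),
                    channels = chdf, bilateral_mode = r$bilateral_mode,
                    deviation_tolerance = r$deviation_tolerance,
                    min_step = r$min_step,
                    introduced_on_day = r$introduced_on_day,
                    demo_repetitions = r$demo_repetitions)
  })
}
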