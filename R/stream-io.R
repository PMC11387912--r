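#' Write / read motion streams as record-per-line text
#'
#' One JSON record per line per tracked frame: `timestamp`,
#' `view_direction`, and per-hand joint angles (degrees), orientation
#' (row-major 3x3) and wrist position. The round trip preserves the data
#' at full double precision.
#'
#' @param frames List of [tracked_frame()]s.
#' @param path File path.
#' @return `read_motion_jsonl()` returns a list of `tracked_frame`s;
#'   `write_motion_jsonl()` returns `path` invisibly.
#' @section Errors: `handrehab_parse_error` with the offending line number.
#' @export
write_motion_jsonl <- function(frames, path) {
  hand_rec <- function(h) {
    if (is.null(h)) return(NULL)
    list(side = h$side, joint_angles = as.list(h$joint_angles),
         orientation = as.numeric(t(h$orientation)),
         wrist_position = h$wrist_position)
  }
  lines <- vapply(frames, function(fr) {
    rec <- list(timestamp = fr$timestamp,
                view_direction = fr$view_direction)
    if (!is.null(fr$left)) rec$left <- hand_rec(fr$left)
    if (!is.null(fr$right)) rec$right <- hand_rec(fr$right)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_motion_jsonl
#' @export
read_motion_jsonl <- function(path) {
  if (!file.exists(path))
    hr_stop(sprintf("stream file not found: %s", path), "handrehab_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rec_hand <- function(r) {
    if (is.null(r)) return(NULL)
    hand_pose(r$side, unlist(r$joint_angles),
              orientation = matrix(unlist(r$orientation), 3, 3, byrow = TRUE),
              wrist_position = unlist(r$wrist_position))
  }
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) hr_stop(
                      sprintf("malformed frame at line %d of %s: %s", i, path,
                              conditionMessage(e)), "handrehab_parse_error"))
    tryCatch(
      tracked_frame(rec$timestamp, left = rec_hand(rec$left),
                    right = rec_hand(rec$right),
                    view_direction = unlist(rec$view_direction)),
      handrehab_error = function(e) hr_stop(
        sprintf("invalid frame at line %d of %s: %s", i, path,
                conditionMessage(e)), "handrehab_parse_error"))
  })
}

#' Read a motion stream from a delimited table
#'
#' Ingest for wide-table exports: one row per frame with a `timestamp`
#' column, optional `view_x`/`view_y`/`view_z` columns, and one column per
#' joint named `<side>_<joint>` (e.g. `right_index_mcp`), angles in
#' degrees. Orientation-dependent (wrist) channels are not representable
#' in this format; hands present are those with a complete 15-joint
#' column set.
#'
#' @param path Delimited text file.
#' @param sep Field separator; default `","`.
#' @return List of [tracked_frame()]s.
#' @export
read_motion_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"timestamp" %in% names(df))
    hr_stop("stream table needs a 'timestamp' column", "handrehab_parse_error")
  joints <- canonical_joints()
  sides <- Filter(function(s) all(paste(s, joints, sep = "_") %in% names(df)),
                  c("left", "right"))
  if (!length(sides))
    hr_stop("stream table holds no complete 15-joint hand column set",
            "handrehab_parse_error")
  has_view <- all(c("view_x", "view_y", "view_z") %in% names(df))
  lapply(seq_len(nrow(df)), function(i) {
    hands <- lapply(sides, function(s) {
      ang <- as.numeric(df[i, paste(s, joints, sep = "_")])
      hand_pose(s, setNames(ang, joints))
    })
    names(hands) <- sides
    vd <- if (has_view) unitize(as.numeric(df[i, c("view_x", "view_y", "view_z")]))
          else c(0, 0, 1)
    tracked_frame(df$timestamp[i], left = hands$left, right = hands$right,
                  view_direction = vd)
  })
}
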