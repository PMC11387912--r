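#' Hand pose: per-joint flexion angles plus hand orientation
#'
#' Snapshot of one hand at one instant, as delivered by an optical
#' hand-tracking source reduced to the canonical 15-joint flexion model.
#'
#' @param side `"left"` or `"right"`.
#' @param joint_angles Named numeric vector covering exactly the canonical
#'   joint set ([canonical_joints()]), degrees of flexion.
#' @param orientation 3x3 proper rotation matrix (hand-to-world); default
#'   identity.
#' @param wrist_position Numeric length-3, meters; default origin.
#' @param joint_range Anatomical range check applied to every angle
#'   (degrees, default 0 to 110).
#'
#' @return A `hand_pose` object.
#' @export
#' @examples
#' ang <- setNames(rep(10, 15), canonical_joints())
#' hand_pose("right", ang)
hand_pose <- function(side, joint_angles, orientation = diag(3),
                      wrist_position = c(0, 0, 0),
                      joint_range = c(0, 110)) {
  side <- match.arg(side, c("left", "right"))
  want <- canonical_joints()
  if (!setequal(names(joint_angles), want))
    hr_stop("joint_angles must cover exactly the 15 canonical joints",
            "handrehab_bad_pose")
  joint_angles <- joint_angles[want]
  if (any(!is.finite(joint_angles)))
    hr_stop("non-finite joint angle", "handrehab_bad_pose")
  if (any(joint_angles < joint_range[1] - 1e-9 |
          joint_angles > joint_range[2] + 1e-9))
    hr_stop(sprintf("joint angle outside anatomical range [%g, %g] deg",
                    joint_range[1], joint_range[2]), "handrehab_bad_pose")
  check_rotation(orientation)
  stopifnot(length(wrist_position) == 3L, all(is.finite(wrist_position)))
  structure(list(side = side, joint_angles = joint_angles,
                 orientation = orientation,
                 wrist_position = as.numeric(wrist_position)),
            class = "hand_pose")
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R)))
    hr_stop("orientation must be a finite 3x3 matrix", "handrehab_bad_pose")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    hr_stop("orientation is not a proper rotation matrix", "handrehab_bad_pose")
  invisible(R)
}

#' @export
print.hand_pose <- function(x, ...) {
  cat(sprintf("<hand_pose> %s hand, mean flexion %.1f deg\n",
              x$side, mean(x$joint_angles)))
  invisible(x)
}

#' Tracked frame: one timestamped sample of the motion stream
#'
#' @param timestamp Seconds; must be strictly increasing within a stream.
#' @param left,right [hand_pose()] or `NULL` when the hand is untracked.
#' @param view_direction Unit 3-vector, the player's view direction in world
#'   coordinates.
#'
#' @return A `tracked_frame` object.
#' @export
tracked_frame <- function(timestamp, left = NULL, right = NULL,
                          view_direction = c(0, 0, 1)) {
  if (!is_number(timestamp))
    hr_stop("timestamp must be a finite number (seconds)", "handrehab_bad_frame")
  if (abs(vnorm(view_direction) - 1) > 1e-6)
    hr_stop("view_direction must have unit norm (tolerance 1e-6)",
            "handrehab_bad_frame")
  for (h in list(left, right))
    if (!is.null(h) && !inherits(h, "hand_pose"))
      hr_stop("left/right must be hand_pose or NULL", "handrehab_bad_frame")
  structure(list(timestamp = timestamp, left = left, right = right,
                 view_direction = as.numeric(view_direction),
                 valid = c(left = !is.null(left), right = !is.null(right))),
            class = "tracked_frame")
}

#' Construct the wrist reference frame from the view direction
#'
#' The optical tracking model has no forearm bone, so wrist rotation is
#' measured against a frame anchored at the wrist and spanned by the world
#' vertical axis and the player's view direction leveled into the horizontal
#' plane (its vertical component set to zero). The third (lateral) axis is
#' the cross product of the first two, giving a right-handed orthonormal
#' triad. The construction assumes the forearm is held roughly along the
#' view direction.
#'
#' @param view_direction Unit 3-vector.
#' @param vertical Unit 3-vector, world up; default `c(0, 1, 0)` (the usual
#'   VR y-up convention).
#' @param wrist_position 3-vector, meters; frame origin.
#' @param margin_deg Minimum angle (degrees) the view direction must keep
#'   from the vertical; below it the leveled direction is considered
#'   degenerate. Default 5.
#'
#' @return A `wrist_frame` with fields `origin`, `forward_axis`,
#'   `lateral_axis`, `up_axis`.
#' @section Errors: condition class `handrehab_degenerate_view` when the
#'   player looks within `margin_deg` of straight up or down; callers should
#'   fall back to the last valid frame.
#' @export
#' @examples
#' compute_wrist_frame(c(0, 0, 1))
compute_wrist_frame <- function(view_direction, vertical = c(0, 1, 0),
                                wrist_position = c(0, 0, 0),
                                margin_deg = 5) {
  view_direction <- unitize(view_direction)
  vertical <- unitize(vertical)
  leveled <- view_direction - sum(view_direction * vertical) * vertical
  if (vnorm(leveled) < sin(deg2rad(margin_deg)))
    hr_stop(sprintf(
      "view direction within %g deg of vertical: leveled direction degenerate",
      margin_deg), "handrehab_degenerate_view")
  forward <- leveled / vnorm(leveled)
  lateral <- cross3(vertical, forward)   # right-handed: lateral = up x forward
  structure(list(origin = as.numeric(wrist_position),
                 forward_axis = forward,
                 lateral_axis = lateral,
                 up_axis = vertical),
            class = "wrist_frame")
}

frame_basis <- function(frame) {
  cbind(frame$forward_axis, frame$lateral_axis, frame$up_axis)
}

#' Decompose a hand orientation into wrist rotation angles
#'
#' Expresses the hand orientation relative to the wrist reference frame and
#' decomposes it, in a fixed roll-pitch-yaw order, into pronation (roll
#' about the forward axis), flexion (pitch about the lateral axis) and
#' radial/ulnar deviation (yaw about the up axis), all in degrees.
#'
#' @param pose A [hand_pose()].
#' @param frame A `wrist_frame` from [compute_wrist_frame()].
#' @return A `wrist_angles` list with fields `pronation`, `flexion`,
#'   `deviation`, each in (-180, 180].
#' @seealso [recompose_orientation()] for the inverse map.
#' @export
wrist_angles <- function(pose, frame) {
  check_rotation(pose$orientation)
  B <- frame_basis(frame)
  R <- t(B) %*% pose$orientation %*% B   # rotation in frame-local coordinates
  # R = Rz(yaw) Ry(pitch) Rx(roll) with local x = forward, y = lateral, z = up
  pitch <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(abs(R[3, 1]) - 1) < 1e-12) {   # gimbal: pitch at +/-90, fold into roll
    roll <- atan2(-R[2, 3], R[2, 2])
    yaw <- 0
  } else {
    roll <- atan2(R[3, 2], R[3, 3])
    yaw <- atan2(R[2, 1], R[1, 1])
  }
  structure(list(pronation = rad2deg(roll), flexion = rad2deg(pitch),
                 deviation = rad2deg(yaw)),
            class = "wrist_angles")
}

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Recompose a world orientation from wrist angles
#'
#' Inverse of [wrist_angles()]: builds the hand-to-world rotation whose
#' decomposition in `frame` yields the given pronation/flexion/deviation.
#'
#' @param angles A `wrist_angles` object or numeric length-3
#'   (pronation, flexion, deviation) in degrees.
#' @param frame A `wrist_frame`.
#' @return 3x3 rotation matrix.
#' @export
recompose_orientation <- function(angles, frame) {
  if (inherits(angles, "wrist_angles"))
    angles <- c(angles$pronation, angles$flexion, angles$deviation)
  B <- frame_basis(frame)
  R <- rot_z(deg2rad(angles[3])) %*% rot_y(deg2rad(angles[2])) %*%
    rot_x(deg2rad(angles[1]))
  B %*% R %*% t(B)
}

#' Extract the normalized feature vector of a pose
#'
#' Maps each channel of `channels` onto \[0, 1\] by its declared range:
#' joint channels read the pose's flexion angles, wrist channels the
#' decomposed wrist rotation (which requires a valid `frame`). Values are
#' clamped to \[0, 1\].
#'
#' @param pose A [hand_pose()].
#' @param channels A [channel_spec()].
#' @param frame A `wrist_frame`, required when `channels` includes wrist
#'   channels.
#' @return Named numeric vector, one entry per channel, in \[0, 1\].
#' @section Errors: `handrehab_missing_channel` when a requested joint is
#'   absent from the pose or a wrist channel is requested without a frame.
#' @export
pose_to_features <- function(pose, channels, frame = NULL) {
  stopifnot(inherits(pose, "hand_pose"), is_channel_spec(channels))
  wr <- channels$channel %in% wrist_channels()
  vals <- numeric(nrow(channels))
  if (any(!wr)) {
    idx <- match(channels$channel[!wr], names(pose$joint_angles))
    if (anyNA(idx))
      hr_stop(paste0("pose lacks requested joint(s): ",
                     paste(channels$channel[!wr][is.na(idx)], collapse = ", ")),
              "handrehab_missing_channel")
    vals[!wr] <- pose$joint_angles[idx]
  }
  if (any(wr)) {
    if (is.null(frame))
      hr_stop("wrist channels requested but no wrist frame supplied",
              "handrehab_missing_channel")
    wa <- wrist_angles(pose, frame)
    wav <- c(wrist_pronation = wa$pronation, wrist_flexion = wa$flexion,
             wrist_deviation = wa$deviation)
    vals[wr] <- wav[channels$channel[wr]]
  }
  f <- (vals - channels$lo) / (channels$hi - channels$lo)
  f <- pmin(1, pmax(0, f))
  names(f) <- channels$channel
  f
}

#' Reconstruct a hand pose from a feature vector
#'
#' Inverse of [pose_to_features()] up to clamping: joint features map back
#' to flexion angles through the channel ranges; wrist features (if present)
#' are recomposed into the hand orientation via `frame`. Joints not covered
#' by `channels` are set to the channel range minimum.
#'
#' Used by the virtual-patient simulator to turn feature-space trajectories
#' into full tracked frames.
#'
#' @param features Named numeric vector in \[0, 1\] (names = channels).
#' @param channels A [channel_spec()].
#' @param side `"left"` or `"right"`.
#' @param frame A `wrist_frame`; required when wrist channels are present.
#' @return A [hand_pose()].
#' @export
features_to_pose <- function(features, channels, side = "right", frame = NULL) {
  stopifnot(is_channel_spec(channels), length(features) == nrow(channels))
  features <- pmin(1, pmax(0, features))
  vals <- channels$lo + features * (channels$hi - channels$lo)
  names(vals) <- channels$channel
  wr <- names(vals) %in% wrist_channels()
  ang <- setNames(rep(0, 15), canonical_joints())
  ang[names(vals)[!wr]] <- vals[!wr]
  # joints outside the spec stay at 0; ranges with lo > 0 still land in-range
  jr <- range(c(0, channels$lo[!wr], channels$hi[!wr]))
  orientation <- diag(3)
  if (any(wr)) {
    if (is.null(frame))
      hr_stop("wrist channels present but no wrist frame supplied",
              "handrehab_missing_channel")
    wa <- c(wrist_pronation = 0, wrist_flexion = 0, wrist_deviation = 0)
    wa[names(vals)[wr]] <- vals[wr]
    orientation <- recompose_orientation(
      c(wa[["wrist_pronation"]], wa[["wrist_flexion"]], wa[["wrist_deviation"]]),
      frame)
  }
  hand_pose(side, ang, orientation = orientation,
            joint_range = c(min(jr[1], 0), max(jr[2], 110)))
}
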