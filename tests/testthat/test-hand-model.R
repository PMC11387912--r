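test_that("wrist frame construction levels the view direction", {
  fr <- compute_wrist_frame(c(0, 0, 1))
  expect_equal(fr$forward_axis, c(0, 0, 1))
  expect_equal(fr$up_axis, c(0, 1, 0))
  expect_equal(abs(fr$lateral_axis), c(1, 0, 0))

  # tilted view: vertical component removed, then renormalized
  fr2 <- compute_wrist_frame(c(0, 0.6, 0.8))
  expect_equal(fr2$forward_axis, c(0, 0, 1), tolerance = 1e-12)

  expect_error(compute_wrist_frame(c(0, 1, 0)),
               class = "handrehab_degenerate_view")
  # just inside the 5-degree margin is still degenerate
  v <- c(sin(4 * pi / 180), cos(4 * pi / 180), 0)
  expect_error(compute_wrist_frame(v), class = "handrehab_degenerate_view")
})

test_that("wrist frame is orthonormal for random non-degenerate views", {
  set.seed(42)
  for (i in 1:200) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    fr <- tryCatch(compute_wrist_frame(v),
                   handrehab_degenerate_view = function(e) NULL)
    if (is.null(fr)) next
    B <- cbind(fr$forward_axis, fr$lateral_axis, fr$up_axis)
    expect_lt(max(abs(crossprod(B) - diag(3))), 1e-6)
    expect_equal(det(B), 1, tolerance = 1e-6)
    expect_equal(fr$forward_axis[2], 0)  # forward has zero vertical component
  }
})

test_that("wrist angle decomposition matches its recomposition (round trip)", {
  fr <- compute_wrist_frame(c(0.3, 0.1, 0.9))
  ang0 <- setNames(rep(0, 15), canonical_joints())

  # identity orientation -> all angles zero
  wa <- wrist_angles(hand_pose("right", ang0), fr)
  expect_equal(c(wa$pronation, wa$flexion, wa$deviation), c(0, 0, 0),
               tolerance = 1e-9)

  # pure roll about the forward axis
  R <- rotation_about(fr$forward_axis, 90)
  wa <- wrist_angles(hand_pose("right", ang0, orientation = R), fr)
  expect_equal(wa$pronation, 90, tolerance = 1e-9)
  expect_equal(wa$flexion, 0, tolerance = 1e-9)
  expect_equal(wa$deviation, 0, tolerance = 1e-9)

  # random rotations: decompose-then-recompose reproduces the rotation
  set.seed(7)
  for (i in 1:100) {
    R <- random_rotation()
    wa <- wrist_angles(hand_pose("right", ang0, orientation = R), fr)
    R2 <- recompose_orientation(wa, fr)
    expect_lt(max(abs(R - R2)), 1e-6)
  }
})

test_that("pose_to_features normalizes linearly by channel range", {
  ch <- channel_spec()
  lo <- hand_pose("right", setNames(rep(0, 15), canonical_joints()))
  hi <- hand_pose("right", setNames(rep(110, 15), canonical_joints()))
  mid <- hand_pose("right", setNames(rep(55, 15), canonical_joints()))
  expect_equal(unname(pose_to_features(lo, ch)), rep(0, 15))
  expect_equal(unname(pose_to_features(hi, ch)), rep(1, 15))
  expect_equal(unname(pose_to_features(mid, ch)), rep(0.5, 15))
  expect_named(pose_to_features(lo, ch), ch$channel)
})

test_that("pose_to_features is monotone per channel", {
  ch <- channel_spec()
  set.seed(11)
  for (i in 1:25) {
    base <- runif(15, 0, 100)
    j <- sample(15, 1)
    bumped <- base
    bumped[j] <- base[j] + runif(1, 0, 10)
    f1 <- pose_to_features(hand_pose("right", setNames(base, canonical_joints())), ch)
    f2 <- pose_to_features(hand_pose("right", setNames(bumped, canonical_joints())), ch)
    expect_gte(f2[j], f1[j])
    expect_equal(f2[-j], f1[-j])
  }
})

test_that("wrist channels require a frame and feed through the decomposition", {
  chw <- channel_spec(wrist = TRUE)
  pose <- hand_pose("right", setNames(rep(0, 15), canonical_joints()))
  expect_error(pose_to_features(pose, chw), class = "handrehab_missing_channel")
  fr <- compute_wrist_frame(c(0, 0, 1))
  f <- pose_to_features(pose, chw, frame = fr)
  # identity orientation = 0 degrees = middle of the -90..90 range
  expect_equal(unname(f[wrist_channels()]), rep(0.5, 3))

  pose90 <- hand_pose("right", setNames(rep(0, 15), canonical_joints()),
                      orientation = rotation_about(fr$forward_axis, 90))
  f90 <- pose_to_features(pose90, chw, frame = fr)
  expect_equal(unname(f90["wrist_pronation"]), 1)
})

test_that("features_to_pose inverts pose_to_features", {
  chw <- channel_spec(wrist = TRUE)
  fr <- compute_wrist_frame(c(0, 0, 1))
  set.seed(3)
  for (i in 1:20) {
    f <- setNames(runif(18, 0.05, 0.95), chw$channel)
    pose <- features_to_pose(f, chw, frame = fr)
    expect_equal(pose_to_features(pose, chw, frame = fr), f, tolerance = 1e-9)
  }
})

test_that("pose and frame constructors enforce their invariants", {
  expect_error(hand_pose("right", setNames(rep(0, 14), canonical_joints()[-1])),
               class = "handrehab_bad_pose")
  expect_error(hand_pose("right", setNames(c(200, rep(0, 14)), canonical_joints())),
               class = "handrehab_bad_pose")
  expect_error(hand_pose("right", setNames(rep(0, 15), canonical_joints()),
                         orientation = diag(3) * 2),
               class = "handrehab_bad_pose")
  expect_error(tracked_frame(0, view_direction = c(1, 1, 0)),
               class = "handrehab_bad_frame")
  p <- hand_pose("left", setNames(rep(5, 15), canonical_joints()))
  fr <- tracked_frame(0.5, left = p)
  expect_true(fr$valid[["left"]])
  expect_false(fr$valid[["right"]])
})
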