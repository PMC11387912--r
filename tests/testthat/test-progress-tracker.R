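test_that("progress maps the keyframes to their path parameters", {
  ex <- fist_exercise()
  expect_equal(progress(feat(0), ex), 0)      # start position
  expect_equal(progress(feat(1), ex), 1)      # end position
  expect_equal(progress(feat(0.5), ex), 0.5)  # on-path midpoint

  ex3 <- fist3_exercise()
  expect_equal(progress(feat(0.5), ex3), 0.5) # middle keyframe of 3
  expect_equal(progress(feat(1), ex3), 1)
})

test_that("off-path positions beyond the tolerance map to -1", {
  ex <- fist_exercise(tolerance = 0.25)
  mid <- oracle_path_point(ex, 0.5)
  off <- orthogonal_offset(ex, 0.5)
  displaced <- mid + 2 * ex$deviation_tolerance * off
  expect_equal(progress(unname(displaced), ex), -1)
  # just inside the tolerance still projects onto the path
  near <- mid + 0.9 * ex$deviation_tolerance * off
  expect_equal(progress(unname(near), ex), 0.5, tolerance = 1e-9)
})

test_that("progress equals the dense brute-force projection oracle", {
  set.seed(101)
  for (i in 1:25) {
    ex <- random_exercise(n_kf = sample(2:4, 1))
    for (j in 1:4) {
      x <- if (j %% 2 == 0) {
        # near-path point: on-path plus sub-tolerance noise
        p <- runif(1)
        oracle_path_point(ex, p) + runif(15, -0.05, 0.05)
      } else feat(runif(15))
      got <- progress(unname(x), ex)
      want <- oracle_progress(x, ex)
      if (want < 0) expect_equal(got, -1)
      else expect_lt(abs(got - want), 1e-3)
    }
  }
})

test_that("progress is monotone along the path for on-path inputs", {
  set.seed(33)
  for (i in 1:10) {
    ex <- random_exercise(n_kf = 3)
    ps <- sort(runif(20))
    vals <- vapply(ps, function(p)
      progress(unname(oracle_path_point(ex, p)), ex), numeric(1))
    expect_true(all(diff(vals) >= -1e-9))
  }
})

test_that("bilateral progress combines hands per mode", {
  ex_sync <- define_exercise("s", "sync", pose_keyframe("start", feat(0)),
                             pose_keyframe("end", feat(1)), channels = ch15,
                             bilateral_mode = "synchronous")
  ex_opp <- define_exercise("o", "opp", pose_keyframe("start", feat(0)),
                            pose_keyframe("end", feat(1)), channels = ch15,
                            bilateral_mode = "opposite")
  expect_equal(bilateral_progress(feat(1), feat(1), ex_sync), 1)
  expect_equal(bilateral_progress(feat(1), feat(0.6), ex_sync), 0.6)
  # opposite: left at end while right is back at start scores full progress
  expect_equal(bilateral_progress(feat(1), feat(0), ex_opp), 1)
  expect_equal(bilateral_progress(feat(0), feat(1), ex_opp), 0)
  # a deviating hand dominates
  dev <- unname(oracle_path_point(ex_sync, 0.5) +
                  2 * ex_sync$deviation_tolerance * orthogonal_offset(ex_sync))
  expect_equal(bilateral_progress(dev, feat(0.5), ex_sync), -1)
  expect_error(bilateral_progress(NULL, feat(0.5), ex_sync),
               class = "handrehab_missing_hand")
  expect_error(bilateral_progress(feat(0), feat(0), fist_exercise()),
               class = "handrehab_bad_argument")
})

test_that("repetition machine segments clean excursions", {
  # triangle wave 0 -> 1 -> 0, target 0.6: one recognized repetition
  ts <- seq(0, 4, by = 0.05)
  vals <- 1 - abs(ts - 2) / 2
  ev <- segment_repetitions(ts, vals, target = 0.6)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$recognized)
  expect_equal(ev$peak_progress, 1)

  # peak below target: the event is logged but not recognized
  ev2 <- segment_repetitions(ts, 0.4 * vals, target = 0.6)
  expect_equal(nrow(ev2), 1L)
  expect_false(ev2$recognized)
  expect_equal(ev2$peak_progress, 0.4, tolerance = 1e-9)

  # below the low threshold nothing ever starts
  ev3 <- segment_repetitions(ts, 0.1 * vals, target = 0.6)
  expect_equal(nrow(ev3), 0L)
})

test_that("sustained deviation resets the running peak", {
  ts <- c(0.0, 0.2, 0.4, 0.6, 2.0, 2.2, 2.4, 2.6)
  vals <- c(0.0, 0.5, 0.9, -1, -1, 0.5, 0.3, 0.1)   # -1 sustained 1.4 s
  ev <- segment_repetitions(ts, vals, target = 0.8)
  expect_equal(nrow(ev), 1L)
  expect_false(ev$recognized)        # the 0.9 peak was discarded
  expect_lt(ev$peak_progress, 0.8)

  # a brief (<1 s) deviation keeps the peak
  ts2 <- c(0.0, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  vals2 <- c(0.0, 0.5, 0.9, -1, 0.5, 0.3, 0.1)
  ev2 <- segment_repetitions(ts2, vals2, target = 0.8)
  expect_equal(nrow(ev2), 1L)
  expect_true(ev2$recognized)
})

test_that("noiseless cycle counts are exact for 1..60 cycles", {
  ex <- fist_exercise()
  pt <- virtual_patient(jitter_sd = 0, deviation_prob = 0,
                        improvement_rate = 0, rep_duration_cv = 0,
                        rep_duration_mean = 2, frame_rate = 30)
  set.seed(12)
  for (k in c(1:10, 25, 60)) {
    run <- simulate_exercise_run(pt, ex, n_reps = k)
    tr <- track_exercise(run, ex, target = 0.55)
    expect_equal(nrow(tr$events), k)
    expect_equal(sum(tr$events$recognized), k)
  }
})

test_that("seeded jitter does not cause double counting over 10 cycles", {
  ex <- fist_exercise()
  pt <- virtual_patient(jitter_sd = 0.02, deviation_prob = 0,
                        improvement_rate = 0, rep_duration_mean = 3)
  for (seed in 1:5) {
    set.seed(seed)
    run <- simulate_exercise_run(pt, ex, n_reps = 10)
    tr <- track_exercise(run, ex, target = 0.55)
    expect_equal(sum(tr$events$recognized), 10L)
  }
})

test_that("tracking a frozen start pose yields no events", {
  ex <- fist_exercise()
  X <- matrix(rep(feat(0.01), each = 100), nrow = 100)
  tr <- track_exercise(X, ex, target = 0.5, timestamps = seq_len(100) / 30)
  expect_equal(nrow(tr$events), 0L)
  expect_true(all(tr$samples$value >= 0 & tr$samples$value < 0.05))
})

test_that("tracker recovers generator ground truth end to end", {
  ex <- fist_exercise()
  pt <- virtual_patient(jitter_sd = 0, deviation_prob = 0,
                        improvement_rate = 0, rep_duration_mean = 3,
                        rep_duration_cv = 0.1, frame_rate = 30)
  set.seed(9)
  run <- simulate_exercise_run(pt, ex, n_reps = 40)
  tr <- track_exercise(run, ex, target = 0.55)
  expect_equal(nrow(tr$events), nrow(run$truth))
  # inter-event periods recover the configured cycle duration within 5%
  periods <- diff(tr$events$end_time)
  expect_lt(abs(mean(periods) - pt$rep_duration_mean) / pt$rep_duration_mean,
            0.05)
  # tracked peaks match the day's ROM limit
  expect_lt(max(abs(tr$events$peak_progress - run$truth$peak)), 0.01)
})

test_that("full tracked-frame streams give identical results to matrix streams", {
  ex <- fist_exercise()
  pt <- virtual_patient(jitter_sd = 0, deviation_prob = 0,
                        improvement_rate = 0, rep_duration_cv = 0,
                        rep_duration_mean = 2, frame_rate = 20)
  set.seed(4)
  run <- simulate_exercise_run(pt, ex, n_reps = 3)
  frames <- stream_frames(run)
  tr_m <- track_exercise(run, ex, target = 0.55)
  tr_f <- track_exercise(frames, ex, target = 0.55)
  expect_equal(tr_f$samples$value, tr_m$samples$value, tolerance = 1e-9)
  expect_equal(nrow(tr_f$events), nrow(tr_m$events))
})
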