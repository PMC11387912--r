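test_that("initial ROM is the peak of the calibration pass", {
  pt <- virtual_patient(jitter_sd = 0, deviation_prob = 0,
                        improvement_rate = 0, rom_limit_0 = 0.7,
                        rom_limit_max = 0.7, rep_duration_cv = 0)
  ex <- fist_exercise()
  set.seed(2)
  cal <- simulate_repetition(pt, ex, day = 1)
  tr <- track_exercise(cal, ex, target = 0.5)
  expect_equal(measure_initial_rom(tr$samples), 0.7, tolerance = 1e-3)

  expect_equal(measure_initial_rom(c(-1, 0.2, 0.65, 0.3)), 0.65)
  expect_equal(measure_initial_rom(c(0.5, 1.0)), 1)      # full range
  expect_equal(measure_initial_rom(c(0, 0.01)), 0.05)    # clamped floor
  expect_error(measure_initial_rom(c(-1, -1)),
               class = "handrehab_no_valid_samples")
})

test_that("daily targets follow the fixed and adaptive policies", {
  h <- list(rom_record("fist", 1, c(0.55, 0.65)),   # day mean 0.6
            rom_record("fist", 2, c(0.75, 0.85)))   # day mean 0.8
  # adaptive: mean of preceding day means
  t3 <- daily_target(h, initial = 0.5, day = 3, policy = "adaptive_daily")
  expect_equal(t3$target, 0.7)
  # fixed policy ignores history
  tf <- daily_target(h, initial = 0.5, day = 3, policy = "fixed_initial")
  expect_equal(tf$target, 0.5)
  # day 1 falls back to the initial measurement
  t1 <- daily_target(list(), initial = 0.5, day = 1, policy = "adaptive_daily")
  expect_equal(t1$target, 0.5)
  # lower clamp: a collapsed history cannot drag the target below initial/2
  hbad <- list(rom_record("fist", 1, 0.1))
  tb <- daily_target(hbad, initial = 0.8, day = 2, policy = "adaptive_daily")
  expect_equal(tb$target, 0.4)
  # other exercises' records are ignored
  hmix <- c(h, list(rom_record("other", 1, 0.95)))
  tm <- daily_target(hmix, initial = 0.5, day = 3, policy = "adaptive_daily",
                     exercise_id = "fist")
  expect_equal(tm$target, 0.7)
  # sliding window restricts the history
  hw <- list(rom_record("fist", 1, 0.2), rom_record("fist", 2, 0.6),
             rom_record("fist", 3, 0.8))
  tw <- daily_target(hw, initial = 0.6, day = 4, policy = "adaptive_daily",
                     window = 2)
  expect_equal(tw$target, 0.7)
})

test_that("adaptive targets equal the running mean for a noiseless improving patient", {
  pt <- virtual_patient(jitter_sd = 0, deviation_prob = 0, rom_limit_0 = 0.5,
                        rom_limit_max = 0.9, improvement_rate = 0.2)
  initial <- rom_on_day(pt, 1)
  hist <- lapply(1:11, function(d) rom_record("fist", d, rom_on_day(pt, d)))
  for (d in 2:12) {
    tgt <- daily_target(hist[seq_len(d - 1)], initial, d, "adaptive_daily")
    expect_equal(tgt$target,
                 mean(vapply(1:(d - 1), function(dd) rom_on_day(pt, dd),
                             numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("traffic light categories cut the exceedance range at thirds", {
  expect_equal(as.character(traffic_color(-1, 0.6)$category), "neutral")
  expect_equal(as.character(traffic_color(0.5, 0.6)$category), "neutral")
  expect_equal(as.character(traffic_color(0.6, 0.6)$category), "red")
  e_third <- 0.6 + (1 - 0.6) / 3
  expect_equal(as.character(traffic_color(e_third - 1e-9, 0.6)$category), "red")
  expect_equal(as.character(traffic_color(e_third + 1e-9, 0.6)$category), "orange")
  expect_equal(as.character(traffic_color(0.6 + 2 * (1 - 0.6) / 3, 0.6)$category),
               "green")
  expect_equal(as.character(traffic_color(1, 0.6)$category), "green")
  # target already at the ceiling: reaching it is red, never an error
  expect_equal(as.character(traffic_color(1, 1)$category), "red")
})

test_that("traffic light is monotone in progress", {
  lv <- c("neutral", "red", "orange", "green")
  for (tgt in c(0.3, 0.6, 0.9, 1)) {
    ps <- seq(0, 1, by = 0.01)
    cats <- vapply(ps, function(p)
      match(as.character(traffic_color(p, tgt)$category), lv), integer(1))
    expect_true(all(diff(cats) >= 0))
  }
})

test_that("score points scale linearly with achieved ROM", {
  ev <- function(peak) list(peak_progress = peak, recognized = TRUE)
  expect_equal(score_points(ev(1)), 100L)
  expect_equal(score_points(ev(0.5)), 50L)
  expect_equal(score_points(ev(0.734)), 73L)
  # full-ROM players get identical maximal scores on every exercise
  expect_equal(vapply(1:6, function(i) score_points(ev(1)), integer(1)),
               rep(100L, 6))
  expect_error(score_points(list(peak_progress = 0.9, recognized = FALSE)),
               class = "handrehab_bad_argument")
})

test_that("ROM progression report is chronological per exercise", {
  expect_equal(nrow(rom_progress_report(list())), 0L)
  h <- list(rom_record("fist", 2, c(0.7, 0.9)),
            rom_record("fist", 1, c(0.5, 0.7)),
            rom_record("hook", 1, 0.6))
  rep_ <- rom_progress_report(h)
  expect_equal(nrow(rep_), 3L)
  fr <- rep_[rep_$exercise_id == "fist", ]
  expect_equal(fr$day, c(1L, 2L))
  expect_equal(fr$mean_peak, c(0.6, 0.8))
  expect_equal(fr$max_peak, c(0.7, 0.9))

  # an improving noiseless patient yields non-decreasing day means
  pt <- virtual_patient(jitter_sd = 0, improvement_rate = 0.3)
  h2 <- lapply(1:12, function(d) rom_record("fist", d, rom_on_day(pt, d)))
  r2 <- rom_progress_report(h2)
  expect_true(all(diff(r2$mean_peak) >= 0))
})
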