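make_log <- function(day_completes, rep_durations = NULL) {
  # day_completes: named numeric, day -> number of completed stations
  evs <- list()
  t <- 0
  for (d in as.integer(names(day_completes))) {
    t <- t + 1
    evs[[length(evs) + 1]] <- session_event(t, "session_start", day = d)
    for (i in seq_len(day_completes[[as.character(d)]])) {
      t <- t + 1
      evs[[length(evs) + 1]] <- session_event(t, "station_complete", day = d,
                                              station_id = sprintf("s%d", i))
    }
    if (!is.null(rep_durations))
      for (dur in rep_durations) {
        t <- t + 1
        evs[[length(evs) + 1]] <- session_event(t, "repetition", day = d,
                                                station_id = "s1",
                                                exercise_id = "fist",
                                                duration = dur, peak = 0.8,
                                                recognized = TRUE)
      }
    t <- t + 1
    evs[[length(evs) + 1]] <- session_event(t, "session_end", day = d)
  }
  do.call(rbind, evs)
}

test_that("event logs round trip through record-per-line text", {
  log <- make_log(c(`1` = 2, `2` = 3), rep_durations = c(4.5, 5.25))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_log(log, path)
  back <- parse_log(path)
  expect_equal(back$kind, log$kind)
  expect_equal(back$timestamp, log$timestamp)
  expect_equal(back$duration, log$duration)
  expect_equal(back$day, log$day)
  expect_equal(back$recognized, log$recognized)

  empty <- withr::local_tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_equal(nrow(parse_log(empty)), 0L)
})

test_that("malformed log lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"timestamp": 1, "kind": "session_start", "day": 1}',
               "{{{ not json"), path)
  err <- tryCatch(parse_log(path), error = function(e) e)
  expect_s3_class(err, "handrehab_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("stations per day summarizes mean and SE across subjects", {
  # every subject completes exactly 2 stations daily -> mean 2, SE 0
  logs <- list(make_log(c(`1` = 2, `2` = 2)), make_log(c(`1` = 2, `2` = 2)))
  s <- stations_per_day(logs)
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$se, c(0, 0))
  expect_equal(s$n, c(2L, 2L))

  # subjects completing {2, 4} on a day -> mean 3, SE 1
  logs2 <- list(make_log(c(`1` = 2)), make_log(c(`1` = 4)))
  s2 <- stations_per_day(logs2)
  expect_equal(s2$mean, 3)
  expect_equal(s2$se, 1)
})

test_that("repetition durations aggregate subject means before the cohort mean", {
  logs <- list(make_log(c(`1` = 1), rep_durations = rep(5, 4)),
               make_log(c(`1` = 1), rep_durations = rep(5, 4)))
  r <- rep_duration_per_day(logs)
  expect_equal(r$mean, 5)
  expect_equal(r$se, 0)

  # two subjects at 4 s and 6 s -> mean 5, SE 1
  logs2 <- list(make_log(c(`1` = 1), rep_durations = rep(4, 3)),
                make_log(c(`1` = 1), rep_durations = rep(6, 5)))
  r2 <- rep_duration_per_day(logs2)
  expect_equal(r2$mean, 5)
  expect_equal(r2$se, 1)
})

test_that("cohort metrics agree with a brute-force recount on simulated logs", {
  trial <- simulate_trial(n_subjects = 4L, days = 3L, seed = 77)
  s <- stations_per_day(trial$logs)
  r <- rep_duration_per_day(trial$logs)
  for (d in unique(s$day)) {
    # independent recount straight off the raw event rows
    counts <- vapply(trial$logs, function(ev)
      sum(ev$kind == "station_complete" & ev$day == d), numeric(1))
    expect_equal(s$mean[s$day == d], mean(counts))
    expect_equal(s$se[s$day == d], sd(counts) / sqrt(length(counts)))
    submeans <- vapply(trial$logs, function(ev)
      mean(ev$duration[ev$kind == "repetition" & ev$day == d]), numeric(1))
    expect_equal(r$mean[r$day == d], mean(submeans), tolerance = 1e-12)
  }
})

test_that("SUS scoring follows the standard 0-100 transform", {
  expect_equal(score_questionnaire("SUS", c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)), 100)
  expect_equal(score_questionnaire("SUS", rep(3, 10)), 50)
  expect_equal(score_questionnaire("SUS", rep(1, 10)), 50)  # odd 0, even 4 each
  df <- data.frame(item = 10:1, score = c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5))
  expect_equal(score_questionnaire("SUS", df), 100)   # item order respected
  expect_error(score_questionnaire("SUS", rep(3, 9)),
               class = "handrehab_incomplete_response")
  expect_error(score_questionnaire("SUS", c(rep(3, 9), 7)),
               class = "handrehab_incomplete_response")
})

test_that("IMI and MARS score subscale means with reverse coding", {
  imi <- data.frame(subscale = rep(c("interest", "pressure"), each = 3),
                    item = paste0("q", 1:6),
                    score = c(6, 6, 6, 2, 3, 4))
  s <- score_questionnaire("IMI", imi)
  expect_equal(s[["interest"]], 6)
  expect_equal(s[["pressure"]], 3)
  # reverse-coded item: 8 - score on the 1-7 scale
  s2 <- score_questionnaire("IMI", imi, reverse_items = "q4")
  expect_equal(s2[["pressure"]], mean(c(8 - 2, 3, 4)))

  mars <- data.frame(subscale = rep("engagement", 4), item = paste0("m", 1:4),
                     score = c(4, 4, 5, 4))
  expect_equal(score_questionnaire("MARS", mars)[["engagement"]], 4.25)
  expect_error(score_questionnaire("MARS",
                                   transform(mars, score = c(4, 4, 6, 4))),
               class = "handrehab_incomplete_response")
})
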