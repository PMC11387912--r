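Package: handrehab
Title: Keyframed Hand-Exercise Tracking and Adaptive Range-of-Motion Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-independent engine for virtual-reality hand and finger
    rehabilitation games. Exercises are defined as keyframed paths through a
    normalized joint-flexion feature space; live hand-motion streams are mapped
    to a progress scalar in [0,1] (with -1 flagging deviation from the
    movement), segmented into repetitions, and scored against fixed or
    daily-adaptive range-of-motion targets with traffic-light biofeedback.
    Includes the station/daily-task/unlock exergame protocol, session event-log
    analytics (stations per day, repetition durations, SUS/IMI/MARS
    questionnaire scoring), and a seeded virtual-patient simulator that
    generates multi-day hand-motion streams with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
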