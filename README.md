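# handrehab

A hardware-independent engine for VR hand- and finger-rehabilitation
exergames, for researchers and developers who need the computational core
of such a game — exercise definition, live movement tracking, adaptive
difficulty, protocol scheduling, analytics — without a headset, a game
engine, or patients.

After a traumatic hand injury, recovery depends on daily repetitive
exercises whose monotony erodes adherence. Rehabilitation games counter
this by tracking the hand optically and wrapping the exercises in
feedback and reward loops. `handrehab` implements that loop end to end on
plain joint-angle streams:

* **Exercises as keyframed paths.** A movement is an ordered set of stored
  hand positions (start, optional middles, end) in a normalized feature
  space of 15 joint-flexion channels (thumb CMC/MCP/IP, four fingers ×
  MCP/PIP/DIP) plus 3 wrist-rotation channels measured against a reference
  frame built from the leveled view direction (consumer trackers have no
  forearm bone).
* **The progress scalar.** Each frame's feature vector *x* is projected
  onto the piecewise-linear keyframe path; the path parameter is the
  progress *p* ∈ [0, 1] — 0 at the start position, 1 at the end position —
  and *p* = −1 when the weighted distance to the path exceeds the
  deviation tolerance (the hand left the movement).
* **Repetitions and recognition.** A hysteresis state machine segments the
  progress stream into repetitions with peak and duration; a repetition is
  *recognized* iff its peak reaches the player's ROM target.
* **Adaptive ROM targets and Traffic Light feedback.** The target is the
  initially measured personal ROM (fixed policy) or is recalculated daily
  as the mean ROM achieved over the preceding days (adaptive policy);
  reaching it turns the virtual hands red, and exceedance by thirds of the
  remaining range turns them orange then green.
* **Protocol scheduling.** Stations of 6 exercises × 10 repetitions,
  2 mandatory daily tasks, one station unlocked per fulfilled day up to 12,
  new exercises on days 1/4/7/10 of the 12-session protocol (plus the
  4-session prototype variant).
* **Analytics.** Record-per-line session event logs; stations/day and
  repetition-duration/day as cohort mean (SE); standard SUS/IMI/MARS
  questionnaire scoring.
* **Virtual patients.** A seeded simulator generates multi-day cohorts with
  improving ROM (exponential saturation), log-normal repetition durations,
  tracking jitter, off-path deviations and imperfect compliance — with
  ground truth, so every layer above is testable.

## Worked example

```r
library(handrehab)

lib <- builtin_library("v1")        # 17 movements, introduced days 1/4/7/10
ex  <- lib[[1]]
ex
#> <exercise_definition> fist ("Close the hand into a fist"): 2 keyframes, single, day 1

## A virtual patient with 60% initial ROM, improving toward 95%
patient <- virtual_patient(rom_limit_0 = 0.6, rom_limit_max = 0.95,
                           improvement_rate = 0.15, seed = 42)

## Day 1: calibration pass -> initially measured ROM
set.seed(42)
cal <- simulate_repetition(patient, ex, day = 1)
initial <- measure_initial_rom(track_exercise(cal, ex, target = 0.5)$samples)
initial
#> [1] 0.613

## Day 5: track ten repetitions against that target
run <- simulate_exercise_run(patient, ex, day = 5, n_reps = 10)
tr  <- track_exercise(run, ex, target = initial)
head(tr$events[, c("start_time", "end_time", "peak_progress", "recognized")], 3)
#>   start_time  end_time peak_progress recognized
#> 1  0.3338419  4.890784     0.7658279       TRUE
#> 2  5.6084456 10.831792     0.7741050       TRUE
#> 3 11.5821285 16.863989     0.7677911       TRUE
sum(tr$events$recognized)
#> [1] 10
nrow(tr$events)
#> [1] 11
```

The patient's day-5 ROM limit (≈0.77) exceeds the day-1 target, so all ten
true repetitions are recognized; the eleventh logged event is a simulated
off-path deviation — logged, but not recognized and not counted toward any
quota.

```r
## Version-2 adaptive targeting and traffic-light feedback
hist <- list(rom_record(ex$id, 1, 0.60), rom_record(ex$id, 2, 0.66))
tgt  <- daily_target(hist, initial = initial, day = 3, policy = "adaptive_daily")
tgt$target                                    # mean of preceding day ROMs
#> [1] 0.63
as.character(traffic_color(0.80, tgt)$category)
#> [1] "orange"
as.character(traffic_color(0.95, tgt)$category)
#> [1] "green"

## A 5-subject, 12-day cohort with full compliance
trial <- simulate_trial(n_subjects = 5, days = 12, seed = 7)
head(stations_per_day(trial$logs), 3)
#>   day mean se n           metric
#> 1   1    2  0 5 stations_per_day
#> 2   2    2  0 5 stations_per_day
#> 3   3    2  0 5 stations_per_day
head(rep_duration_per_day(trial$logs), 3)
#>   day     mean        se n         metric
#> 1   1 5.845287 0.3887971 5 rep_duration_s
#> 2   2 5.766782 0.3824495 5 rep_duration_s
#> 3   3 5.788013 0.3817725 5 rep_duration_s
vapply(trial$subjects, `[[`, numeric(1), "unlocked")
#> [1] 12 12 12 12 12
```

Every compliant subject completes the 2 mandatory stations per day
(mean 2, SE 0), repetition durations scatter around the configured
log-normal means, and fulfilling the daily tasks on all 12 days unlocks
all 12 stations.

See `vignettes/handrehab-methods.Rmd` for the model details, parameter
rationale, and the simulator's scope and limitations.

## Command line

A thin wrapper over the same functions lives at `inst/cli/handrehab.R`:

```sh
Rscript inst/cli/handrehab.R library  --version v1 --out lib.json
Rscript inst/cli/handrehab.R simulate --subjects 5 --days 12 --seed 1 --out-dir cohort/
Rscript inst/cli/handrehab.R report   --log-dir cohort/ --out summary.csv
Rscript inst/cli/handrehab.R schedule --variant v1 --seed 1 --day 3
Rscript inst/cli/handrehab.R track    --stream s.jsonl --library lib.json \
                                      --exercise fist --target 0.6 --out run
```

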