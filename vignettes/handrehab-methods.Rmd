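---
title: "handrehab: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{handrehab: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handrehab)
```

## The problem

Hand and finger rehabilitation after trauma requires daily, repetitive
exercising, and adherence collapses quickly when the exercises are boring or
painful. VR exergames address this by wrapping the exercises in a game: an
optical hand tracker supplies per-frame joint flexion angles, the game
measures how far along a prescribed movement the patient's hand is, counts
repetitions, adapts the difficulty to the patient's personal range of motion
(ROM), and schedules a multi-week protocol of themed exercise "stations"
with daily tasks and unlockable rewards.

`handrehab` implements that computational core as a hardware-independent
engine: everything between the tracking data and the rendered game. It
consumes joint-angle streams (from any source) and produces progress
samples, repetition events, adaptive targets, traffic-light feedback
categories, protocol state and session analytics. A seeded virtual-patient
simulator generates realistic multi-day input streams with ground truth, so
every layer can be validated end to end without hardware or patients.

## Hand model and the wrist reference frame

A hand pose is reduced at ingest to 15 flexion channels — thumb CMC/MCP/IP
plus MCP/PIP/DIP for each long finger — with a configurable anatomical
range per hinge joint (default 0–110°), plus the hand's orientation as a
rotation matrix. Coordinates are right-handed with world **+Y up** (the
usual VR convention); both are configurable.

Consumer hand-tracking models have no forearm bone, so wrist rotation
cannot be read off a bone chain. The engine instead constructs a reference
frame at the wrist: the up axis is the world vertical; the forward axis is
the player's view direction *leveled* by removing its vertical component
and renormalizing; the lateral axis is their cross product. The hand
orientation expressed in this frame is decomposed in a fixed
roll–pitch–yaw order into pronation (about forward), flexion (about
lateral) and radial/ulnar deviation (about up), in degrees. The
decomposition order is a convention we fix once; round-trip tests
(decompose, recompose, compare) pin it down within the principal domain
(pitch in ±90°). The construction assumes the forearm points roughly along
the view direction — the posture the game instructs. When the player looks
within 5° of straight up or down the leveled direction is degenerate; the
engine raises a typed condition and the caller keeps the last valid frame.

Features are angles normalized linearly to [0, 1] per channel by its
declared range (wrist channels default to −90..90°), so every exercise
lives in a common unit feature space. All feature-space distances are
weight-normalized RMS, `d(a,b) = sqrt(sum(w (a−b)²) / sum(w))`, which keeps
tolerances comparable across channel subsets of different size.

## Exercises as keyframed paths and the progress scalar

An exercise is an ordered path of pose keyframes — start, optional middles,
end — recorded from stable windows of a live stream (per-channel median;
a window whose per-channel IQR exceeds 0.1 is rejected as "hand was
moving"). Keyframe *k* of *K* sits at path parameter (k−1)/(K−1); a
3-keyframe definition therefore puts its middle position at 0.5. Paths must
have positive length: consecutive keyframes closer than 0.05 in feature
distance are rejected.

Live tracking projects each frame's feature vector orthogonally onto the
globally nearest point of the piecewise-linear path (in the weighted
metric) and reports the path parameter as the progress scalar: 0 at the
start position, 1 at the end position. If the distance to the path exceeds
the exercise's deviation tolerance (default 0.25), the pose does not belong
to the movement and the scalar is −1. Global (rather than
sequential-segment) nearest-point search is the simplest reading of how a
middle keyframe sharpens the mapping; a brute-force dense-sampling oracle
(10⁴ path samples) agrees with the closed-form projection to 10⁻³ on
randomized exercises in the test suite. Ties between segments resolve to
the smaller parameter.

Bilateral modes combine per-hand scalars: synchronous is
`min(p_left, p_right)`; opposite evaluates the right hand against the
reversed path, `min(p_left, 1 − p_right)`; a deviating hand dominates
(−1). A missing required hand is an error, not a zero.

## Repetition segmentation

A hysteresis state machine (idle → advancing → returning → idle) turns the
progress stream into repetition events. Defaults: the start region ends at
0.15 (low threshold); the returning phase begins when progress drops 0.1
below the running peak; the event is emitted when progress re-enters the
start region. Both constants are configurable; they were chosen so that
per-channel tracking jitter of σ = 0.02 — which projects to roughly
σ/√C on the path parameter — cannot toggle phases, and the suite verifies
exact counts for 1..100 noiseless cycles and for seeded jittered streams.
A repetition whose peak misses the ROM target is logged but not
*recognized* (it does not advance quotas), matching the observation that
some patients' movements were not recognized by the game. Deviation
samples pause the machine rather than aborting the repetition; a deviation
sustained beyond 1 s discards the running peak, so a movement that went
off-path through its peak cannot be credited. Event `duration` is the time
between the low-threshold crossings (the machine's own start/end); on
contiguous cycles the inter-event period equals the full cycle time, which
is what the session analytics report.

## Adaptive ROM targets, traffic light, scoring

On first encountering an exercise the engine measures the player's initial
ROM as the maximum progress of a calibration pass (clamped to [0.05, 1]).
Version-1 behaviour keeps that as a fixed target; version-2 behaviour
recalculates the target daily as the mean over preceding days of each
day's mean repetition peak ("average ROM achieved in the preceding days").
Design choices where the source design is open:

* the daily aggregate is the mean of per-repetition peaks;
* the adaptive mean uses the full history by default, with a sliding
  `window` exposed;
* the target is clamped below by half the initial measurement, so a single
  bad day cannot collapse the requirement — the design brief prioritized
  preventing frustration;
* day 1 (no history) falls back to the initial measurement.

The traffic-light feedback maps progress to neutral/red/orange/green:
reaching the target turns the hands red (a recognized repetition), and the
exceedance fraction e = (progress − target)/(1 − target) is cut at thirds
— red below 1/3, orange below 2/3, green above. The thirds and the neutral
below-target colour are our choices; only the colour sequence and the
red-at-target anchor are prescribed. The map is monotone in progress by
construction. Prototype scoring is reconstructed as
`round(100 · peak_progress)` points per recognized repetition — linear in
achieved ROM, so full-range players always score the maximum, which is
exactly the observed weakness of that scoring design.

## Protocol scheduling

A station is 6 exercises × 10 repetitions = 60 recognized repetitions;
completion requires exactly the quota (the 59th repetition never
completes, extra repetitions earn no credit). Each day assigns 2 mandatory
stations, drawn round-robin from the unlocked set with a seed-driven
offset. Fulfilling both mandatory tasks unlocks one additional station per
day (v1/v2) until all 12 are revealed; the prototype variant instead runs
4 sessions over 3 stations, with the third unlocked across days 1–3 and
playable on day 4. New exercises enter on days 1, 4, 7 and 10 of the
12-session protocol. Two open points are fixed as fixtures and documented
as such: the initially unlocked set is 2 stations (the minimum supporting
2 daily tasks), and the station→exercise assignment cycles the day-1
exercise roster deterministically. Under full compliance the unlock-count
sequence over the 12 days is 2, 3, …, 12 — verified in the suite.

## Session analytics and questionnaires

Sessions emit record-per-line JSON event logs (session/station
start/complete, per-repetition duration and peak). Analytics are pure
functions of the logs: stations completed per day and per-repetition
duration per day, summarized across subjects as mean and standard error
(SE = SD/√n). For durations, each subject's repetitions are first averaged
per day and the cohort mean/SE is taken over subject means — the "mean
(SE) across subjects" convention; pooling all repetitions instead would
weight fast subjects more. Questionnaire scoring implements the
instruments' standard rules (SUS 0–100 transform; IMI/MARS subscale means
with configurable reverse-coding keys, since administered item variants
differ between studies). Inferential statistics on cohort data are out of
scope; the summaries are tidy tables ready for any statistics environment.

## The virtual patient

The simulator is the package's ground-truth source, emulating what the
engine assumes about its input, not finger biomechanics. A patient has a
per-day ROM limit with exponential saturation,
`rom(d) = rom0 + (rom_max − rom0)(1 − exp(−λ(d−1)))`, log-normal
repetition durations (mean and CV configurable), additive Gaussian
per-channel feature jitter, a per-repetition probability of an off-path
deviation (displaced beyond tolerance through the middle half of the
cycle, covering the peak), and a daily task-compliance probability.
Defaults — rom0 = 0.6, rom_max = 0.95, λ = 0.15/day, 6 s mean duration
with CV 0.2, jitter σ = 0.02, deviation probability 0.05, full compliance,
60 Hz frames — describe a markedly impaired but improving in-patient over
a 12-session program at a typical HMD tracking rate; the duration scale
matches the several-seconds-per-repetition regime reported for supervised
VR hand therapy. Within a repetition the progress profile is a half-sine
sweep along the keyframe path.

What the generator does **not** emulate: systematic (non-random) deviation
patterns, fatigue or pain dynamics, tracking dropout, inter-finger
coupling, or voluntary play beyond the mandatory tasks. Passing tests
therefore show the engine is correct for streams with these statistical
properties, not that it is robust to every artifact of real optical
tracking. Randomness uses R's default Mersenne-Twister generator; all
simulators are deterministic under a fixed seed.

Streams are generated in feature space (matrix form) and materialized into
full per-frame pose objects only on request; the tracker accepts both
forms and the suite verifies they give identical results.

## Numerical choices and degenerate inputs

* Feature values and path parameters are clamped to [0, 1]; floating-point
  spill at path ends (e.g. sin(π) < 0) is guarded.
* Orthonormality and proper-rotation checks use a 10⁻⁶ tolerance.
* Euler extraction handles the gimbal case (|pitch| = 90°) by folding yaw
  into roll.
* Segment ties in the projection resolve to the earlier segment.
* An all-deviation calibration pass, an empty stream, a locked station, a
  day past the protocol, an incomplete questionnaire, and a foreign
  library schema each raise a typed condition rather than returning a
  guess.

## Problem sizes in the suite

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path with comfortable statistical margins: repetition-counting
exactness over 1..100 cycles at 30 Hz and 2 s cycles; oracle equivalence
on 100 randomized exercises at 10⁴ path samples; parameter recovery on a
homogeneous 10-subject, 12-day cohort (5% tolerances sit many standard
errors from the configured values at these sizes).

## Known limitations

* The 17 version-1 movements are synthesized named placeholders with the
  documented structure (6 basics, wrist/precision, compound, bilateral);
  the clinically curated list is not public.
* The station→exercise mapping and initial unlock set are fixtures.
* Progress projection is global nearest-point: a path that folds back on
  itself in feature space could alias; the keyframe-separation check
  mitigates but does not preclude this.
* Wrist angles are only meaningful while the forearm tracks the view
  direction; the engine flags, but cannot correct, degenerate viewing.
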