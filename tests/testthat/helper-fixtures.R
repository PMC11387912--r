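# shared fixtures and independent oracles

ch15 <- channel_spec()

feat <- function(x, channels = ch15) {
  setNames(rep_len(x, nrow(channels)), channels$channel)
}

# simple open-hand -> fist exercise over the 15 joint channels
fist_exercise <- function(tolerance = 0.25) {
  define_exercise("fist", "Close the fist",
                  pose_keyframe("start", feat(0)),
                  pose_keyframe("end", feat(1)),
                  channels = ch15, deviation_tolerance = tolerance)
}

# 3-keyframe variant with an explicit middle position
fist3_exercise <- function(middle = 0.5) {
  define_exercise("fist3", "Close the fist (3 keyframes)",
                  pose_keyframe("start", feat(0)),
                  pose_keyframe("end", feat(1)),
                  middles = list(pose_keyframe("middle", feat(middle))),
                  channels = ch15)
}

# a random multi-keyframe exercise with well-separated keyframes
random_exercise <- function(n_kf = 3L, channels = ch15, min_step = 0.05) {
  repeat {
    kfs <- lapply(seq_len(n_kf), function(i)
      pose_keyframe(if (i == 1L) "start" else if (i == n_kf) "end" else "middle",
                    feat(stats::runif(nrow(channels)), channels)))
    ok <- tryCatch({
      define_exercise("rnd", "random", kfs[[1]], kfs[[n_kf]],
                      middles = if (n_kf > 2L) kfs[2:(n_kf - 1L)] else list(),
                      channels = channels, min_step = min_step)
    }, handrehab_degenerate_path = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
}

# independent weighted-RMS distance (mirrors the documented metric)
oracle_dist <- function(a, b, w) sqrt(sum(w * (a - b)^2) / sum(w))

# brute-force progress oracle: dense sampling of the piecewise-linear path
oracle_progress <- function(x, exercise, n_grid = 1e4) {
  kfs <- lapply(exercise$keyframes, `[[`, "features")
  K <- length(kfs)
  w <- exercise$channels$weight
  s <- seq(0, 1, length.out = n_grid)
  d <- vapply(s, function(si) {
    u <- si * (K - 1)
    j <- min(K - 1, floor(u) + 1)
    t <- u - (j - 1)
    pt <- kfs[[j]] * (1 - t) + kfs[[j + 1]] * t
    oracle_dist(x, pt, w)
  }, numeric(1))
  i <- which.min(d)
  if (d[i] > exercise$deviation_tolerance) -1 else s[i]
}

# unit vector orthogonal (in the weighted metric) to the path direction at
# parameter p, with unit weighted-RMS norm
orthogonal_offset <- function(exercise, p = 0.5) {
  kfs <- lapply(exercise$keyframes, `[[`, "features")
  K <- length(kfs)
  j <- min(K - 1, floor(p * (K - 1)) + 1)
  d <- kfs[[j + 1]] - kfs[[j]]
  w <- exercise$channels$weight
  u <- rep_len(c(1, -1), length(d))
  u <- u - sum(w * u * d) / sum(w * d^2) * d
  u / sqrt(sum(w * u^2) / sum(w))
}

# point on the path at parameter p (independent linear interpolation)
oracle_path_point <- function(exercise, p) {
  kfs <- lapply(exercise$keyframes, `[[`, "features")
  K <- length(kfs)
  u <- p * (K - 1)
  j <- min(K - 1, floor(u) + 1)
  t <- u - (j - 1)
  kfs[[j]] * (1 - t) + kfs[[j + 1]] * t
}

# drive a game_state through one fully compliant day (all mandatory quotas)
play_day_fully <- function(state) {
  plan <- day_plan(state)
  for (sid in plan$mandatory_tasks)
    for (ex in state$stations[[sid]]$exercise_ids)
      for (i in 1:10)
        state <- register_repetition(state, sid, ex,
                                     list(recognized = TRUE, peak_progress = 0.9))
  advance_day(state, plan)
}

rotation_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

random_rotation <- function() {
  rotation_about(stats::rnorm(3), stats::runif(1, -170, 170))
}
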