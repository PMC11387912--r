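#' Map a hand position onto the exercise path
#'
#' The exercise's keyframes span a piecewise-linear path through normalized
#' feature space; keyframe k of K sits at path parameter (k-1)/(K-1). A
#' hand position is orthogonally projected (in the weighted feature metric)
#' onto the globally nearest point of the path and its parameter is the
#' progress scalar: 0 is the start position, 1 the end position. When the
#' distance to the path exceeds the exercise's deviation tolerance the
#' position does not belong to the movement and -1 is returned.
#'
#' @param features Named numeric feature vector (channels must match the
#'   exercise), or a matrix of such rows for `progress_stream()`.
#' @param exercise An [define_exercise()] definition.
#' @return `progress()`: a single number in \[0, 1\] or -1.
#'   `progress_stream()`: a numeric vector, one value per row.
#' @section Errors: `handrehab_channel_mismatch` when the feature channels
#'   differ from the exercise's channel spec.
#' @export
#' @examples
#' ch <- channel_spec()
#' ex <- define_exercise("fist", "Fist",
#'   pose_keyframe("start", setNames(rep(0, 15), ch$channel)),
#'   pose_keyframe("end", setNames(rep(1, 15), ch$channel)), channels = ch)
#' progress(setNames(rep(0.5, 15), ch$channel), ex)   # 0.5
progress <- function(features, exercise) {
  as.numeric(progress_stream(matrix(check_features(features, exercise),
                                    nrow = 1L), exercise))
}

check_features <- function(features, exercise) {
  ch <- exercise$channels$channel
  if (length(features) != length(ch))
    hr_stop("feature vector length does not match exercise channels",
            "handrehab_channel_mismatch")
  if (!is.null(names(features)) && !identical(names(features), ch))
    hr_stop("feature channel names do not match exercise channels",
            "handrehab_channel_mismatch")
  as.numeric(features)
}

#' @rdname progress
#' @export
progress_stream <- function(features, exercise) {
  stopifnot(inherits(exercise, "exercise_definition"))
  X <- if (is.matrix(features)) features else stream_features(features)
  if (ncol(X) != nrow(exercise$channels))
    hr_stop("feature matrix width does not match exercise channels",
            "handrehab_channel_mismatch")
  P <- keyframe_matrix(exercise)
  w <- exercise$channels$weight
  K <- nrow(P)
  n <- nrow(X)
  best_d2 <- rep(Inf, n)
  best_par <- numeric(n)
  sw <- sum(w)
  for (j in seq_len(K - 1L)) {
    a <- P[j, ]; b <- P[j + 1L, ]
    d <- b - a
    wd <- w * d
    denom <- sum(wd * d)
    t <- (X %*% wd - sum(a * wd)) / denom
    t <- pmin(1, pmax(0, as.numeric(t)))
    # squared weighted distance to the projected point
    proj <- sweep(outer(t, d), 2L, a, "+")
    d2 <- as.numeric((X - proj)^2 %*% w) / sw
    par <- (j - 1L + t) / (K - 1L)
    upd <- d2 < best_d2 - 1e-15
    best_par[upd] <- par[upd]
    best_d2[upd] <- d2[upd]
  }
  out <- best_par
  out[sqrt(best_d2) > exercise$deviation_tolerance] <- -1
  out
}

#' Combine both hands' progress in a bilateral exercise
#'
#' Synchronous mode requires both hands to advance together: progress is
#' the minimum of the two hands. Opposite mode mirrors the right hand's
#' path (the right hand moves end-to-start while the left moves
#' start-to-end), so the pair's progress is `min(p_left, 1 - p_right)`.
#' A deviation (-1) on either hand dominates.
#'
#' @param left,right Feature vectors for the two hands (`NULL` when a hand
#'   is untracked).
#' @param exercise A bilateral [define_exercise()] definition
#'   (`bilateral_mode` of `"synchronous"` or `"opposite"`).
#' @return A single number in \[0, 1\] or -1.
#' @section Errors: `handrehab_missing_hand` when a required hand is
#'   untracked; `handrehab_bad_argument` for single-hand exercises.
#' @export
bilateral_progress <- function(left, right, exercise) {
  mode <- exercise$bilateral_mode
  if (mode == "single")
    hr_stop("bilateral_progress requires a synchronous or opposite exercise",
            "handrehab_bad_argument")
  if (is.null(left) || is.null(right))
    hr_stop("both hands must be tracked for a bilateral exercise",
            "handrehab_missing_hand")
  pl <- progress(left, exercise)
  pr <- progress(right, exercise)
  if (pl < 0 || pr < 0) return(-1)
  if (mode == "synchronous") min(pl, pr) else min(pl, 1 - pr)
}
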