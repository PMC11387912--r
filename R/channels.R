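#' Canonical finger-joint identifiers
#'
#' The engine reduces the headset's hierarchical bone model to 15 flexion
#' channels: three thumb joints (CMC, MCP, IP) and MCP/PIP/DIP for each of
#' the index, middle, ring and little fingers.
#'
#' @return Character vector of the 15 canonical joint ids.
#' @export
canonical_joints <- function() {
  fingers <- c("index", "middle", "ring", "little")
  c("thumb_cmc", "thumb_mcp", "thumb_ip",
    as.vector(t(outer(fingers, c("mcp", "pip", "dip"), paste, sep = "_"))))
}

#' Wrist rotation channel identifiers
#'
#' @return Character vector of the 3 wrist channels (pronation, flexion,
#'   deviation), measured against the constructed wrist reference frame.
#' @export
wrist_channels <- function() {
  c("wrist_pronation", "wrist_flexion", "wrist_deviation")
}

#' Define the feature channels of an exercise
#'
#' A channel spec selects a subset of the 15 canonical joint channels plus
#' (optionally) the 3 wrist rotation channels, and attaches to each a weight
#' and a normalization range in degrees. Joint angles are mapped linearly
#' onto \[0, 1\] by their range; weights enter every feature-space distance
#' used for deviation detection and path projection.
#'
#' @param joints Character vector of joint ids (subset of
#'   [canonical_joints()]); default all 15.
#' @param wrist Logical; include the 3 wrist channels (requires a valid
#'   wrist reference frame when extracting features).
#' @param joint_range Numeric length-2, degrees; normalization range for
#'   hinge joints (default 0 to 110).
#' @param wrist_range Numeric length-2, degrees; normalization range for
#'   wrist rotations (default -90 to 90).
#' @param weights Optional named numeric vector of per-channel weights
#'   (default 1 for every channel).
#'
#' @return A `channel_spec`: data frame with columns `channel`, `weight`,
#'   `lo`, `hi`.
#' @export
#' @examples
#' channel_spec()                       # 15 joint channels
#' channel_spec(wrist = TRUE)           # 15 joints + 3 wrist channels
channel_spec <- function(joints = canonical_joints(), wrist = FALSE,
                         joint_range = c(0, 110), wrist_range = c(-90, 90),
                         weights = NULL) {
  bad <- setdiff(joints, canonical_joints())
  if (length(bad))
    hr_stop(paste0("unknown joint id(s): ", paste(bad, collapse = ", ")),
            "handrehab_bad_argument")
  if (anyDuplicated(joints))
    hr_stop("duplicated joint ids in channel spec", "handrehab_bad_argument")
  stopifnot(length(joint_range) == 2L, diff(joint_range) > 0,
            length(wrist_range) == 2L, diff(wrist_range) > 0)
  ch <- data.frame(
    channel = c(joints, if (wrist) wrist_channels()),
    weight  = 1,
    lo = c(rep(joint_range[1], length(joints)),
           if (wrist) rep(wrist_range[1], 3L)),
    hi = c(rep(joint_range[2], length(joints)),
           if (wrist) rep(wrist_range[2], 3L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(weights)) {
    idx <- match(names(weights), ch$channel)
    if (anyNA(idx))
      hr_stop("weights name channels absent from the spec", "handrehab_bad_argument")
    if (any(weights <= 0))
      hr_stop("channel weights must be positive", "handrehab_bad_argument")
    ch$weight[idx] <- unname(weights)
  }
  class(ch) <- c("channel_spec", "data.frame")
  ch
}

is_channel_spec <- function(x) inherits(x, "channel_spec")

n_channels <- function(channels) nrow(channels)

channels_identical <- function(a, b) {
  identical(a$channel, b$channel) &&
    isTRUE(all.equal(a$weight, b$weight)) &&
    isTRUE(all.equal(a$lo, b$lo)) && isTRUE(all.equal(a$hi, b$hi))
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> %d channels (%d joint, %d wrist)\n",
              nrow(x), sum(!x$channel %in% wrist_channels()),
              sum(x$channel %in% wrist_channels())))
  print.data.frame(x, ...)
  invisible(x)
}
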