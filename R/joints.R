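#' Canonical hand joint-angle names
#'
#' The 16 joint angles tracked by the optical hand tracker, in the fixed
#' order used throughout the package: per finger (Thumb, Index, Middle,
#' Ring, Pinky) the carpometacarpal/metacarpophalangeal flexion (F) and
#' abduction (A) angles plus proximal interphalangeal flexion where
#' tracked.
#'
#' @return character vector of length 16.
#' @export
joint_names <- function() {
  c("TCF", "TCA", "TMF", "TMA",
    "IMF", "IMA", "IPF",
    "MMF", "MMA", "MPF",
    "RMF", "RMA", "RPF",
    "PMF", "PMA", "PPF")
}

# joints belonging to each finger (indices into joint_names())
finger_joints <- function() {
  list(thumb = 1:4, index = 5:7, middle = 8:10, ring = 11:13, pinky = 14:16)
}

#' Default anatomical ranges of motion
#'
#' Per-joint normal range in degrees used to normalize joint-angle errors
#' and to place the neutral rest pose at the range midpoint. Flexion
#' joints default to a 0-90 degree arc, abduction joints to -20..20
#' degrees; these are ordinary range-of-motion figures and are meant to be
#' overridden with study-specific values where available.
#'
#' @return named numeric vector (length 16) of ranges in degrees.
#' @export
default_joint_ranges <- function() {
  jn <- joint_names()
  r <- ifelse(substring(jn, 3, 3) == "A", 40, 90)
  names(r) <- jn
  r
}

# neutral pose: midpoint of the default arcs (45 deg flexion, 0 abduction)
default_rest_pose <- function() {
  jn <- joint_names()
  p <- ifelse(substring(jn, 3, 3) == "A", 0, 45)
  names(p) <- jn
  p
}

#' Default electrode grid layout
#'
#' Maps the 16 unipolar channels onto the 4x4 electrode grid in row-major
#' order. The physical arrangement is hardware metadata, so sessions carry
#' their own layout; this is the default used by the simulator.
#'
#' @param channel_ids optional character vector of 16 channel labels.
#' @return data.frame with columns `channel`, `row`, `col` (rows/cols 1..4).
#' @export
default_grid_layout <- function(channel_ids = sprintf("ch%02d", 1:16)) {
  stopifnot(length(channel_ids) == 16)
  data.frame(channel = as.character(channel_ids),
             row = rep(1:4, each = 4),
             col = rep(1:4, times = 4),
             stringsAsFactors = FALSE)
}

# validate that a layout is a bijection channels -> {1..4} x {1..4}
check_grid_layout <- function(layout, channel_ids) {
  if (!is.data.frame(layout) || !all(c("channel", "row", "col") %in% names(layout))) {
    stop_fmt("grid_layout must be a data.frame with columns channel, row, col")
  }
  if (nrow(layout) != 16) stop_fmt("grid_layout must have 16 rows, got %d", nrow(layout))
  if (!setequal(layout$channel, channel_ids)) {
    stop_fmt("grid_layout channels do not match recording channel ids")
  }
  cells <- paste(layout$row, layout$col)
  if (anyDuplicated(cells) || !all(layout$row %in% 1:4) || !all(layout$col %in% 1:4)) {
    stop_fmt("grid_layout is not a bijection onto the 4x4 grid")
  }
  invisible(layout)
}
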