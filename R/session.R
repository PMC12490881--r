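#' Construct a surface-EMG recording
#'
#' Container for a 16-channel unipolar sEMG time series recorded from a
#' 4x4 electrode grid.
#'
#' @param samples numeric matrix, time x 16 channels, in microvolts.
#' @param fs sampling rate in Hz (default 4000).
#' @param channel_ids 16 channel labels; defaults to `colnames(samples)`
#'   or `ch01..ch16`.
#' @param grid_layout electrode position map, see [default_grid_layout()].
#' @return object of class `semg_recording`.
#' @export
semg_recording <- function(samples, fs = 4000,
                           channel_ids = NULL,
                           grid_layout = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 16) {
    stop_fmt("an sEMG recording must have exactly 16 channels, got %d", ncol(samples))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop_fmt("fs must be a positive scalar")
  if (is.null(channel_ids)) {
    channel_ids <- colnames(samples)
    if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", 1:16)
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != 16 || anyDuplicated(channel_ids)) {
    stop_fmt("channel_ids must be 16 unique labels")
  }
  colnames(samples) <- channel_ids
  if (is.null(grid_layout)) grid_layout <- default_grid_layout(channel_ids)
  check_grid_layout(grid_layout, channel_ids)
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 grid_layout = grid_layout),
            class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d samples x 16 channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Construct a joint-angle kinematic track
#'
#' @param angles numeric matrix, time x 16 joints, in degrees.
#' @param rate sampling rate in Hz.
#' @param joint_names_ the 16 joint labels in canonical order.
#' @return object of class `kinematic_track`.
#' @export
kinematic_track <- function(angles, rate, joint_names_ = joint_names()) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 16) {
    stop_fmt("a kinematic track must have exactly 16 joints, got %d", ncol(angles))
  }
  if (!identical(as.character(joint_names_), joint_names())) {
    stop_fmt("joint names must be the 16 canonical names in order (%s, ...)",
             paste(joint_names()[1:3], collapse = ", "))
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) stop_fmt("rate must be positive")
  colnames(angles) <- joint_names_
  structure(list(angles = angles, rate = rate, joint_names = joint_names_),
            class = "kinematic_track")
}

#' @export
print.kinematic_track <- function(x, ...) {
  cat(sprintf("<kinematic_track> %d samples x 16 joints @ %g Hz (%.2f s)\n",
              nrow(x$angles), x$rate, nrow(x$angles) / x$rate))
  invisible(x)
}

#' Construct a gesture annotation table
#'
#' Ordered list of gesture events. Events must be chronologically sorted
#' and non-overlapping; repetition indices count occurrences of each label.
#'
#' @param events data.frame with columns `label`, `onset`, `offset`
#'   (seconds from the first sEMG sample), `repetition`, `setting`.
#' @return object of class `gesture_annotation` (a data.frame).
#' @export
gesture_annotation <- function(events) {
  need <- c("label", "onset", "offset", "repetition", "setting")
  if (!is.data.frame(events) || !all(need %in% names(events))) {
    stop_fmt("events must be a data.frame with columns %s", paste(need, collapse = ", "))
  }
  events <- events[need]
  events$label <- as.character(events$label)
  events$setting <- as.character(events$setting)
  if (any(events$onset >= events$offset)) {
    bad <- which(events$onset >= events$offset)[1]
    stop_fmt("event %d has onset >= offset", bad)
  }
  if (is.unsorted(events$onset)) stop_fmt("events must be sorted by onset")
  if (nrow(events) > 1) {
    ov <- which(events$onset[-1] < events$offset[-nrow(events)])
    if (length(ov)) {
      stop_fmt("events %d and %d overlap in time", ov[1], ov[1] + 1)
    }
  }
  rownames(events) <- NULL
  class(events) <- c("gesture_annotation", "data.frame")
  events
}

#' Construct a session bundle
#'
#' A synchronized triple of sEMG recording, kinematic track and gesture
#' annotation sharing one time origin (the first sEMG sample).
#'
#' @param semg [semg_recording()].
#' @param kinematics [kinematic_track()].
#' @param annotation [gesture_annotation()].
#' @param subject_id subject label.
#' @param metadata free-form named list (seeds, provenance).
#' @return object of class `session_bundle`.
#' @export
session_bundle <- function(semg, kinematics, annotation,
                           subject_id = "S01", metadata = list()) {
  stopifnot(inherits(semg, "semg_recording"),
            inherits(kinematics, "kinematic_track"),
            inherits(annotation, "gesture_annotation"))
  dur_semg <- nrow(semg$samples) / semg$fs
  dur_kin <- nrow(kinematics$angles) / kinematics$rate
  if (nrow(annotation) && max(annotation$offset) > min(dur_semg, dur_kin) + 1e-9) {
    stop_fmt("annotation extends past the recorded signals (%.2f s > %.2f s)",
             max(annotation$offset), min(dur_semg, dur_kin))
  }
  structure(list(semg = semg, kinematics = kinematics, annotation = annotation,
                 subject_id = as.character(subject_id), metadata = metadata),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> subject %s: %d events, %.1f s sEMG @ %g Hz, kinematics @ %g Hz\n",
              x$subject_id, nrow(x$annotation), nrow(x$semg$samples) / x$semg$fs,
              x$semg$fs, x$kinematics$rate))
  invisible(x)
}
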