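#' Acquisition protocol configuration
#'
#' Describes one cued gesture-repetition session: `n_gestures` distinct
#' gestures, each repeated `n_repetitions` times in randomized order, each
#' repetition held for `hold_duration` seconds and followed by a
#' `pause_duration` second rest. The defaults reproduce the 14 x 7 = 98
#' event protocol with 5 s holds and 3 s pauses.
#'
#' @param n_gestures number of distinct gestures (>= 1).
#' @param n_repetitions repetitions per gesture.
#' @param hold_duration seconds each gesture is held (> 0).
#' @param pause_duration rest between gestures in seconds (>= 0). The
#'   session also opens with one leading pause before the first cue.
#' @param settings the four hand-position condition labels.
#' @param order_seed integer seed for the randomized gesture order.
#' @param cue_jitter_sd optional standard deviation (s) of early-onset
#'   jitter: subjects tend to initiate movement slightly before the cue,
#'   so jitter shifts events earlier while keeping them non-overlapping.
#' @param gestures optional character vector of gesture names
#'   (length `n_gestures`); defaults to [default_gestures()].
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(n_gestures = 14, n_repetitions = 7,
                            hold_duration = 5, pause_duration = 3,
                            settings = c("static1", "static2", "static3", "dynamic"),
                            order_seed = 1L, cue_jitter_sd = 0,
                            gestures = NULL) {
  if (!is_count(n_gestures) || n_gestures < 1) stop_fmt("n_gestures must be a positive count")
  if (!is_count(n_repetitions) || n_repetitions < 1) stop_fmt("n_repetitions must be a positive count")
  if (!is.numeric(hold_duration) || hold_duration <= 0) stop_fmt("hold_duration must be > 0")
  if (!is.numeric(pause_duration) || pause_duration < 0) stop_fmt("pause_duration must be >= 0")
  if (cue_jitter_sd < 0) stop_fmt("cue_jitter_sd must be >= 0")
  if (is.null(gestures)) gestures <- default_gestures(n_gestures)
  gestures <- as.character(gestures)
  if (length(gestures) != n_gestures || anyDuplicated(gestures)) {
    stop_fmt("gestures must be %d unique names", n_gestures)
  }
  structure(list(n_gestures = as.integer(n_gestures),
                 n_repetitions = as.integer(n_repetitions),
                 hold_duration = hold_duration,
                 pause_duration = pause_duration,
                 settings = as.character(settings),
                 order_seed = as.integer(order_seed),
                 cue_jitter_sd = cue_jitter_sd,
                 gestures = gestures),
            class = "protocol_config")
}

#' Default gesture vocabulary
#'
#' Fourteen generic hand-posture names used by the simulator's shipped
#' templates. The vocabulary is fully configurable; these names only fix
#' an ordering for defaults.
#'
#' @param n how many names to return (<= 14 for the shipped set).
#' @return character vector.
#' @export
default_gestures <- function(n = 14) {
  base <- c("fist", "open_palm", "index_point", "two_fingers", "three_fingers",
            "four_fingers", "thumb_up", "pinch", "abduction", "hook",
            "ring_flex", "pinky_flex", "thumb_spread", "adduction")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("gesture%02d", seq_len(n - length(base)) + length(base)))
}

#' Generate a randomized session schedule
#'
#' Lays out `n_gestures * n_repetitions` gesture events in a seeded random
#' order on a common clock: one leading pause, then alternating
#' hold/pause blocks. Repetition indices count occurrences of each gesture
#' in chronological order (1-based).
#'
#' @param config a [protocol_config()].
#' @param setting which condition this session was recorded under.
#' @return a [gesture_annotation()] with `n_gestures * n_repetitions` rows.
#' @export
make_protocol <- function(config = protocol_config(), setting = "static1") {
  stopifnot(inherits(config, "protocol_config"))
  setting <- match.arg(setting, config$settings)
  n_ev <- config$n_gestures * config$n_repetitions
  order_labels <- with_seed(config$order_seed, {
    labs <- sample(rep(config$gestures, config$n_repetitions))
    jit <- if (config$cue_jitter_sd > 0) abs(stats::rnorm(n_ev, 0, config$cue_jitter_sd)) else numeric(n_ev)
    list(labs = labs, jit = jit)
  })
  labs <- order_labels$labs
  cycle <- config$hold_duration + config$pause_duration
  onset_nominal <- config$pause_duration + (seq_len(n_ev) - 1) * cycle
  # early-onset jitter, clipped so events stay in order and non-overlapping
  onset <- onset_nominal - pmin(order_labels$jit, config$pause_duration * 0.9)
  offset <- onset + config$hold_duration
  rep_idx <- stats::ave(seq_along(labs), labs, FUN = seq_along)
  gesture_annotation(data.frame(label = labs, onset = onset, offset = offset,
                                repetition = as.integer(rep_idx),
                                setting = setting,
                                stringsAsFactors = FALSE))
}

#' Total scheduled duration of a protocol
#'
#' @param config a [protocol_config()].
#' @return seconds from session start to the end of the final pause.
#' @export
protocol_duration <- function(config) {
  n_ev <- config$n_gestures * config$n_repetitions
  config$pause_duration + n_ev * (config$hold_duration + config$pause_duration)
}
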