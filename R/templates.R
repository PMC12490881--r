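# Finger involvement codes for the 14 default postures.
# Per finger (thumb, index, middle, ring, pinky): -1 flexed, 0 neutral,
# +1 extended. `abd` codes finger spread: +1 abducted, -1 adducted.
default_gesture_codes <- function() {
  m <- rbind(
    fist         = c(-1, -1, -1, -1, -1),
    open_palm    = c( 1,  1,  1,  1,  1),
    index_point  = c(-1,  1, -1, -1, -1),
    two_fingers  = c(-1,  1,  1, -1, -1),
    three_fingers= c(-1,  1,  1,  1, -1),
    four_fingers = c(-1,  1,  1,  1,  1),
    thumb_up     = c( 1, -1, -1, -1, -1),
    pinch        = c(-1, -1,  0,  0,  0),
    abduction    = c( 0,  1,  1,  1,  1),
    hook         = c( 0, -1, -1, -1, -1),
    ring_flex    = c( 0,  0,  0, -1,  0),
    pinky_flex   = c( 0,  0,  0,  0, -1),
    thumb_spread = c( 1,  1,  0,  0,  0),
    adduction    = c( 0,  1,  1,  1,  1))
  abd <- c(fist = 0, open_palm = 0, index_point = 0, two_fingers = 0,
           three_fingers = 0, four_fingers = 0, thumb_up = 0, pinch = 0,
           abduction = 1, hook = 0, ring_flex = 0, pinky_flex = 0,
           thumb_spread = 1, adduction = -1)
  list(flex = m, abd = abd)
}

#' Gesture template set for the session simulator
#'
#' Bundles, for every gesture in the vocabulary, a 16-joint target angle
#' vector (degrees) and a 16-electrode muscle-activation envelope gain
#' vector (microvolts), together with the dynamics parameters that govern
#' how the simulator renders them: transition ramp time, motion-estimator
#' noise, per-repetition force variability and the electromechanical lag
#' between kinematic onset and sEMG envelope onset.
#'
#' The shipped defaults encode 14 postures as finger involvement patterns
#' (which fingers flex, extend or spread); they are simulator parameters
#' loosely modelled on a sign-alphabet gesture set, not measured values.
#'
#' @param gestures gesture names; defaults to [default_gestures()].
#' @param angles optional gestures x 16 matrix of target angles (degrees).
#' @param gains optional gestures x 16 matrix of nonnegative envelope
#'   gains (microvolts) per electrode.
#' @param rest_pose 16-vector of rest angles; defaults to range midpoints.
#' @param separation multiplier on the default angle excursions and gain
#'   contrasts; the template-similarity difficulty knob.
#' @param gain_scale peak envelope gain in microvolts for the defaults.
#' @param transition_time ramp duration between poses, seconds.
#' @param angle_noise_sd motion-estimator noise SD, degrees.
#' @param force_variability_cv coefficient of variation of the lognormal
#'   per-repetition envelope scale.
#' @param force_drift_sd lognormal SD of the slow within-hold force
#'   drift (common to all channels): without force feedback, contraction
#'   strength wanders even while the pose is static, so the envelope is
#'   modulated by a smooth random factor on a `force_drift_tau` second
#'   timescale.
#' @param force_drift_tau timescale of the within-hold drift, seconds.
#' @param onset_lag sEMG envelope onset lag after kinematic onset, seconds.
#' @return a `gesture_template_set`.
#' @export
gesture_templates <- function(gestures = default_gestures(),
                              angles = NULL, gains = NULL,
                              rest_pose = default_rest_pose(),
                              separation = 1,
                              gain_scale = 40,
                              transition_time = 0.5,
                              angle_noise_sd = 2,
                              force_variability_cv = 0.15,
                              force_drift_sd = 0.12,
                              force_drift_tau = 1,
                              onset_lag = 0.1) {
  gestures <- as.character(gestures)
  ng <- length(gestures)
  if (ng < 1) stop_fmt("need at least one gesture")
  if (length(rest_pose) != 16) stop_fmt("rest_pose must have 16 angles")
  if (transition_time <= 0) stop_fmt("transition_time must be > 0")
  if (is.null(angles) || is.null(gains)) {
    def <- build_default_templates(ng, rest_pose, separation, gain_scale)
    if (is.null(angles)) angles <- def$angles
    if (is.null(gains)) gains <- def$gains
  }
  angles <- as.matrix(angles); gains <- as.matrix(gains)
  if (!all(dim(angles) == c(ng, 16))) stop_fmt("angles must be %d x 16", ng)
  if (!all(dim(gains) == c(ng, 16))) stop_fmt("gains must be %d x 16", ng)
  if (any(gains < 0)) stop_fmt("all envelope gains must be >= 0")
  rownames(angles) <- rownames(gains) <- gestures
  colnames(angles) <- joint_names()
  structure(list(gestures = gestures, angles = angles, gains = gains,
                 rest_pose = stats::setNames(as.numeric(rest_pose), joint_names()),
                 transition_time = transition_time,
                 angle_noise_sd = angle_noise_sd,
                 force_variability_cv = force_variability_cv,
                 force_drift_sd = force_drift_sd,
                 force_drift_tau = force_drift_tau,
                 onset_lag = onset_lag),
            class = "gesture_template_set")
}

# Deterministic construction of the default angle and gain matrices from
# the finger-involvement codes. Flexion joints move rest +/- excursion;
# abduction joints follow the spread code. Envelope gains localize each
# involved finger on the grid: fingers index..pinky map to columns 1..4,
# the thumb to the bottom-left corner; spread adds a row-1/row-4 contrast
# so that abduction and adduction differ electromyographically.
build_default_templates <- function(ng, rest_pose, separation, gain_scale) {
  codes <- default_gesture_codes()
  if (ng > nrow(codes$flex)) {
    stop_fmt("default templates cover at most %d gestures; supply angles/gains", nrow(codes$flex))
  }
  flex <- codes$flex[seq_len(ng), , drop = FALSE]
  abd <- codes$abd[seq_len(ng)]
  fj <- finger_joints()
  jn <- joint_names()
  is_abd_joint <- substring(jn, 3, 3) == "A"
  excursion <- 40 * separation
  angles <- matrix(rep(rest_pose, each = ng), ng, 16)
  for (f in seq_along(fj)) {
    jj <- fj[[f]]
    flexj <- jj[!is_abd_joint[jj]]
    # flexed (-1) -> rest + excursion, extended (+1) -> rest - excursion
    angles[, flexj] <- angles[, flexj, drop = FALSE] - outer(flex[, f], rep(excursion, length(flexj)))
  }
  abdj <- which(is_abd_joint)
  angles[, abdj] <- angles[, abdj, drop = FALSE] + outer(abd, rep(15 * separation, length(abdj)))
  # Envelope gains: each finger recruits a compact, finger-specific patch
  # of the 4x4 grid, with extension and flexion loading spatially distinct
  # regions (extensor compartments vs flexor crosstalk on an
  # extensor-site grid), so that postures differing only in
  # flexion/extension still have distinct activation directions.
  layout <- default_grid_layout()
  ext_centers <- rbind(thumb = c(4, 1), index = c(1, 1), middle = c(1, 2),
                       ring = c(1, 3), pinky = c(1, 4))
  flex_centers <- rbind(thumb = c(4, 2), index = c(3, 1), middle = c(3, 2),
                        ring = c(3, 3), pinky = c(3, 4))
  prof_at <- function(center) exp(-((layout$row - center[1])^2 + (layout$col - center[2])^2) / 0.8)
  gains <- matrix(0, ng, 16)
  for (f in seq_along(fj)) {
    gains <- gains + outer(as.numeric(flex[, f] > 0), prof_at(ext_centers[f, ])) +
      0.7 * outer(as.numeric(flex[, f] < 0), prof_at(flex_centers[f, ]))
  }
  # finger spread / squeeze recruit interosseous-like contrasts on row 2
  gains <- gains + outer(pmax(abd, 0), prof_at(c(2, 1.5))) +
    outer(pmax(-abd, 0), prof_at(c(2, 3.5)))
  gains <- gains / max(gains) * gain_scale
  list(angles = angles, gains = gains)
}

#' @export
print.gesture_template_set <- function(x, ...) {
  cat(sprintf("<gesture_template_set> %d gestures, transition %.2g s, angle noise %.2g deg, force CV %.2g, onset lag %.3g s\n",
              length(x$gestures), x$transition_time, x$angle_noise_sd,
              x$force_variability_cv, x$onset_lag))
  invisible(x)
}

#' sEMG noise model for the session simulator
#'
#' @param carrier_band Hz interval of the band-limited interference-pattern
#'   carrier (default 20-450 Hz).
#' @param line_freqs power-line interference frequencies, Hz.
#' @param line_amps amplitudes (microvolts) for each line frequency.
#' @param baseline_sd white baseline noise SD, microvolts.
#' @param artifact_rate all-channel mechanical spike rate, events/minute.
#' @param artifact_amp spike amplitude, microvolts.
#' @param artifact_duration spike duration, seconds.
#' @return a `noise_model`.
#' @export
noise_model <- function(carrier_band = c(20, 450),
                        line_freqs = c(50, 100),
                        line_amps = c(10, 5),
                        baseline_sd = 3,
                        artifact_rate = 2,
                        artifact_amp = 200,
                        artifact_duration = 0.005) {
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 || carrier_band[2] <= carrier_band[1]) {
    stop_fmt("carrier_band must be an increasing positive Hz interval")
  }
  if (length(line_amps) != length(line_freqs)) stop_fmt("line_amps must match line_freqs")
  if (artifact_rate < 0) stop_fmt("artifact_rate must be >= 0")
  structure(list(carrier_band = carrier_band, line_freqs = line_freqs,
                 line_amps = line_amps, baseline_sd = baseline_sd,
                 artifact_rate = artifact_rate, artifact_amp = artifact_amp,
                 artifact_duration = artifact_duration),
            class = "noise_model")
}
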