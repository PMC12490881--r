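#' Synthesize the kinematic ground-truth track for a session
#'
#' Renders piecewise joint-angle trajectories from an annotation: the rest
#' pose during pauses, a linear ramp of `transition_time` seconds into the
#' gesture's template pose after each onset, a plateau at the template
#' angles during the hold, and a ramp back to rest after the offset.
#' Additive Gaussian noise of SD `angle_noise_sd` emulates optical motion
#' estimator jitter.
#'
#' @param annotation a [gesture_annotation()].
#' @param templates a [gesture_templates()] set covering every label.
#' @param rate output sampling rate, Hz (tracker native rate, e.g. 120).
#' @param duration total track duration in seconds; defaults to the last
#'   offset plus one transition time.
#' @param seed RNG seed for the estimator noise.
#' @return a [kinematic_track()].
#' @export
synth_kinematics <- function(annotation, templates, rate = 120,
                             duration = NULL, seed = 1L) {
  stopifnot(inherits(annotation, "gesture_annotation"),
            inherits(templates, "gesture_template_set"))
  missing_lab <- setdiff(unique(annotation$label), templates$gestures)
  if (length(missing_lab)) {
    stop_fmt("no gesture template for label(s): %s", paste(missing_lab, collapse = ", "))
  }
  tt <- templates$transition_time
  if (is.null(duration)) duration <- max(annotation$offset) + tt
  n <- ceiling(duration * rate)
  tgrid <- (seq_len(n) - 1) / rate
  ang <- matrix(rep(templates$rest_pose, each = n), n, 16)
  for (i in seq_len(nrow(annotation))) {
    tgt <- templates$angles[annotation$label[i], ]
    on <- annotation$onset[i]; off <- annotation$offset[i]
    idx <- which(tgrid >= on & tgrid < off + tt)
    if (!length(idx)) next
    # fraction of the way toward the template pose at each time point
    w <- pmin((tgrid[idx] - on) / tt, 1)
    w <- pmin(w, pmax((off + tt - tgrid[idx]) / tt, 0))
    ang[idx, ] <- (1 - w) %o% templates$rest_pose + w %o% tgt
  }
  if (templates$angle_noise_sd > 0) {
    ang <- ang + with_seed(seed, matrix(stats::rnorm(n * 16, 0, templates$angle_noise_sd), n, 16))
  }
  kinematic_track(ang, rate)
}

# Envelope activation profile for one event on a time grid: ramps up over
# transition_time starting onset_lag after the kinematic onset, holds, and
# ramps down after offset + lag.
envelope_profile <- function(tgrid, onset, offset, lag, tt) {
  up <- pmin(pmax((tgrid - onset - lag) / tt, 0), 1)
  down <- pmin(pmax((offset + lag + tt - tgrid) / tt, 0), 1)
  pmin(up, down)
}

#' Synthesize a 16-channel sEMG recording for a session
#'
#' Per channel, the signal is an envelope-modulated band-limited Gaussian
#' carrier (the standard surrogate for interference-pattern sEMG) plus
#' power-line interference, white baseline noise and optional brief
#' all-channel mechanical spikes. The envelope follows the active
#' gesture's per-electrode gain, scaled per repetition by a lognormal
#' force factor (mean 1, CV `force_variability_cv`), and rises with a
#' short electromechanical lag after the kinematic onset.
#'
#' @param annotation a [gesture_annotation()].
#' @param templates a [gesture_templates()] set.
#' @param noise a [noise_model()].
#' @param fs sampling rate, Hz; must exceed twice the carrier-band top.
#' @param duration total duration in seconds (default: last offset plus
#'   one transition time).
#' @param seed RNG seed; all stochastic components derive from it.
#' @return an [semg_recording()].
#' @export
synth_semg <- function(annotation, templates, noise = noise_model(),
                       fs = 4000, duration = NULL, seed = 1L) {
  stopifnot(inherits(annotation, "gesture_annotation"),
            inherits(templates, "gesture_template_set"),
            inherits(noise, "noise_model"))
  if (fs <= 2 * noise$carrier_band[2]) {
    stop_fmt("fs = %g must exceed twice the carrier band top (%g Hz)", fs, noise$carrier_band[2])
  }
  missing_lab <- setdiff(unique(annotation$label), templates$gestures)
  if (length(missing_lab)) {
    stop_fmt("no gesture template for label(s): %s", paste(missing_lab, collapse = ", "))
  }
  tt <- templates$transition_time
  lag <- templates$onset_lag
  if (is.null(duration)) duration <- max(annotation$offset) + tt
  n <- ceiling(duration * fs)
  tgrid <- (seq_len(n) - 1) / fs
  n_ev <- nrow(annotation)
  cv <- templates$force_variability_cv
  sdlog <- sqrt(log(1 + cv^2))
  rep_scale <- with_seed(derive_seed(seed, "force"), {
    if (cv > 0) stats::rlnorm(n_ev, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, n_ev)
  })
  # per-event envelope profiles (shared across channels), including the
  # slow within-hold force drift: contraction strength wanders even while
  # the pose is static
  drift_sd <- if (is.null(templates$force_drift_sd)) 0 else templates$force_drift_sd
  drift_tau <- if (is.null(templates$force_drift_tau)) 1 else templates$force_drift_tau
  profiles <- vector("list", n_ev)
  ev_idx <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    on <- annotation$onset[i]; off <- annotation$offset[i]
    idx <- which(tgrid >= on + lag & tgrid < off + lag + tt)
    ev_idx[[i]] <- idx
    prof <- envelope_profile(tgrid[idx], on, off, lag, tt) * rep_scale[i]
    if (drift_sd > 0 && length(idx) > 1) {
      tloc <- tgrid[idx]
      knots <- seq(tloc[1], tloc[length(tloc)] + drift_tau, by = drift_tau)
      z <- with_seed(derive_seed(seed, paste0("drift", i)),
                     stats::rnorm(length(knots), -drift_sd^2 / 2, drift_sd))
      prof <- prof * exp(stats::approx(knots, z, xout = tloc, rule = 2)$y)
    }
    profiles[[i]] <- prof
  }
  bp <- signal::butter(4, noise$carrier_band / (fs / 2), type = "pass")
  x <- matrix(0, n, 16)
  any_gain <- any(templates$gains > 0)
  for (ch in 1:16) {
    env <- numeric(n)
    for (i in seq_len(n_ev)) {
      g <- templates$gains[annotation$label[i], ch]
      if (g > 0) env[ev_idx[[i]]] <- env[ev_idx[[i]]] + g * profiles[[i]]
    }
    sig <- numeric(n)
    if (any_gain && any(env > 0)) {
      carrier <- with_seed(derive_seed(seed, paste0("carrier", ch)), stats::rnorm(n))
      carrier <- as.numeric(signal::filtfilt(bp, carrier))
      carrier <- carrier / stats::sd(carrier)
      sig <- env * carrier
    }
    for (k in seq_along(noise$line_freqs)) {
      if (noise$line_amps[k] > 0) {
        ph <- with_seed(derive_seed(seed, paste0("phase", ch, "_", k)), stats::runif(1, 0, 2 * pi))
        sig <- sig + noise$line_amps[k] * sin(2 * pi * noise$line_freqs[k] * tgrid + ph)
      }
    }
    if (noise$baseline_sd > 0) {
      sig <- sig + with_seed(derive_seed(seed, paste0("base", ch)),
                             stats::rnorm(n, 0, noise$baseline_sd))
    }
    x[, ch] <- sig
  }
  if (noise$artifact_rate > 0) {
    spikes <- with_seed(derive_seed(seed, "artifacts"), {
      k <- stats::rpois(1, noise$artifact_rate * duration / 60)
      stats::runif(k, 0, duration)
    })
    w <- max(1L, round(noise$artifact_duration * fs))
    pulse <- noise$artifact_amp * sin(pi * seq_len(w) / (w + 1))
    for (s in spikes) {
      i0 <- floor(s * fs) + 1L
      ii <- i0:min(i0 + w - 1L, n)
      x[ii, ] <- x[ii, ] + pulse[seq_along(ii)]
    }
  }
  semg_recording(x, fs = fs)
}

#' Generate a complete synthetic session
#'
#' Bundles a randomized protocol schedule, the synthesized kinematic
#' ground truth and the synthesized sEMG recording on a shared clock.
#' Every stochastic component (gesture order, estimator noise, carriers,
#' force scales, line phases, artifacts) derives deterministically from
#' `seed`, so identical seeds reproduce bit-identical bundles.
#'
#' @param protocol a [protocol_config()]; its `order_seed` is overridden
#'   by a seed derived from `seed` so one integer pins the whole session.
#' @param templates a [gesture_templates()] set.
#' @param noise a [noise_model()].
#' @param fs sEMG sampling rate, Hz.
#' @param kin_rate kinematic sampling rate, Hz.
#' @param setting condition label for the session.
#' @param subject_id subject label recorded in the bundle.
#' @param seed master seed.
#' @return a [session_bundle()].
#' @export
make_session <- function(protocol = protocol_config(),
                         templates = gesture_templates(),
                         noise = noise_model(),
                         fs = 4000, kin_rate = 120,
                         setting = "static1", subject_id = "S01",
                         seed = 1L) {
  protocol$order_seed <- derive_seed(seed, "order")
  annotation <- make_protocol(protocol, setting = setting)
  duration <- protocol_duration(protocol)
  kin <- synth_kinematics(annotation, templates, rate = kin_rate,
                          duration = duration, seed = derive_seed(seed, "kin"))
  semg <- synth_semg(annotation, templates, noise, fs = fs,
                     duration = duration, seed = derive_seed(seed, "semg"))
  session_bundle(semg, kin, annotation, subject_id = subject_id,
                 metadata = list(seed = as.integer(seed),
                                 generator = "semgdecode::make_session",
                                 fs = fs, kin_rate = kin_rate,
                                 setting = setting))
}
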