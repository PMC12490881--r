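#' Preprocessing configuration
#'
#' Defaults follow standard sEMG practice for grid recordings: power-line
#' notches at 50 and 100 Hz, a fourth-order Butterworth high-pass at
#' 20 Hz, per-channel z-score normalization, and order-1 Savitzky-Golay
#' smoothing (a weighted moving average) with a 502-sample window for the
#' kinematic stream. Filters are applied forward-backward (zero-phase) by
#' default, which squares each stage's magnitude response.
#'
#' @param comb_base_freqs notch frequencies in Hz. By default exactly the
#'   listed frequencies are notched; set `comb_harmonics = TRUE` to also
#'   notch every harmonic up to Nyquist.
#' @param comb_quality notch quality factor Q (centre frequency / -3 dB
#'   bandwidth).
#' @param comb_harmonics extend each base frequency to its harmonics?
#' @param hp_cutoff Butterworth high-pass cutoff, Hz.
#' @param hp_order Butterworth order.
#' @param savgol_window Savitzky-Golay window length in samples; adjusted
#'   to the nearest odd length at use (502 -> 501).
#' @param savgol_polyorder Savitzky-Golay polynomial order.
#' @param zscore z-score each channel over the whole recording?
#' @param zero_phase apply filters forward-backward?
#' @return a `preprocess_config`.
#' @export
preprocess_config <- function(comb_base_freqs = c(50, 100),
                              comb_quality = 30,
                              comb_harmonics = FALSE,
                              hp_cutoff = 20, hp_order = 4,
                              savgol_window = 502, savgol_polyorder = 1,
                              zscore = TRUE, zero_phase = TRUE) {
  if (comb_quality <= 0) stop_fmt("comb_quality must be > 0")
  if (hp_cutoff <= 0) stop_fmt("hp_cutoff must be > 0")
  if (savgol_polyorder >= savgol_window) stop_fmt("savgol_polyorder must be < savgol_window")
  structure(list(comb_base_freqs = comb_base_freqs, comb_quality = comb_quality,
                 comb_harmonics = comb_harmonics,
                 hp_cutoff = hp_cutoff, hp_order = hp_order,
                 savgol_window = savgol_window, savgol_polyorder = savgol_polyorder,
                 zscore = zscore, zero_phase = zero_phase),
            class = "preprocess_config")
}

# Second-order IIR notch (constrained biquad), standard audio-EQ design:
# unit gain at DC and Nyquist, zero at f0, -3 dB bandwidth f0/Q.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# frequencies actually notched for a config at a given sampling rate
notch_freqs <- function(config, fs) {
  fr <- config$comb_base_freqs
  if (isTRUE(config$comb_harmonics)) {
    fr <- unlist(lapply(config$comb_base_freqs, function(f0) seq(f0, fs / 2 - 1e-9, by = f0)))
  }
  sort(unique(fr[fr < fs / 2]))
}

#' Filter and normalize an sEMG recording
#'
#' Applies, in order: power-line notch filters at the configured
#' frequencies, the Butterworth high-pass, and optional per-channel
#' z-score normalization (each channel mean-centered and scaled to unit
#' variance over the whole recording). With `zero_phase = TRUE` every IIR
#' stage runs forward and backward, so its effective magnitude response is
#' squared and no phase distortion is introduced.
#'
#' A constant (zero-variance) channel cannot be z-scored; it is returned
#' as all zeros with a warning.
#'
#' @param recording an [semg_recording()].
#' @param config a [preprocess_config()].
#' @return a filtered [semg_recording()] of the same shape.
#' @export
filter_semg <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "semg_recording"))
  check_finite_matrix(recording$samples, "sEMG samples")
  fs <- recording$fs
  if (config$hp_cutoff >= fs / 2) stop_fmt("hp_cutoff must be below Nyquist (%g Hz)", fs / 2)
  notches <- lapply(notch_freqs(config, fs), design_notch, fs = fs, Q = config$comb_quality)
  hp <- signal::butter(config$hp_order, config$hp_cutoff / (fs / 2), type = "high")
  x <- recording$samples
  out <- x
  for (ch in seq_len(ncol(x))) {
    v <- x[, ch]
    for (nf in notches) {
      v <- if (config$zero_phase) as.numeric(signal::filtfilt(nf$b, nf$a, v))
           else as.numeric(signal::filter(nf$b, nf$a, v))
    }
    v <- if (config$zero_phase) as.numeric(signal::filtfilt(hp, v))
         else as.numeric(signal::filter(hp, v))
    out[, ch] <- v
  }
  if (isTRUE(config$zscore)) {
    mu <- colMeans(out)
    sdv <- apply(out, 2, stats::sd)
    flat <- sdv <= .Machine$double.eps * 100
    if (any(flat)) {
      warning(sprintf("channel(s) %s are constant after filtering; z-score returns zeros",
                      paste(recording$channel_ids[flat], collapse = ", ")))
      sdv[flat] <- 1
      mu[flat] <- out[1, flat]
    }
    out <- sweep(sweep(out, 2, mu), 2, sdv, "/")
  }
  semg_recording(out, fs = fs, channel_ids = recording$channel_ids,
                 grid_layout = recording$grid_layout)
}

#' Smooth a kinematic track with a Savitzky-Golay filter
#'
#' Order-1 Savitzky-Golay smoothing is a weighted moving average; it
#' preserves constants and (in the window interior) linear ramps while
#' attenuating estimator jitter. Even window lengths are adjusted down to
#' the nearest odd length, as the symmetric formulation requires.
#'
#' @param track a [kinematic_track()].
#' @param config a [preprocess_config()] (only the `savgol_*` fields are
#'   used).
#' @return a smoothed [kinematic_track()] of the same shape and rate.
#' @export
smooth_kinematics <- function(track, config = preprocess_config()) {
  stopifnot(inherits(track, "kinematic_track"))
  n <- config$savgol_window
  if (n %% 2 == 0) n <- n - 1
  if (nrow(track$angles) <= n) {
    stop_fmt("track has %d samples but the smoothing window needs more than %d; use a smaller savgol_window",
             nrow(track$angles), n)
  }
  sm <- apply(track$angles, 2, signal::sgolayfilt, p = config$savgol_polyorder, n = n)
  kinematic_track(sm, rate = track$rate)
}

#' Resample a kinematic track by linear interpolation
#'
#' Interpolates every joint trajectory onto a new sampling grid (typically
#' the sEMG clock, so window targets can be read off at sample indices).
#' Endpoints are held beyond the original support.
#'
#' @param track a [kinematic_track()].
#' @param target_fs new sampling rate in Hz.
#' @param n_out optional exact number of output samples.
#' @return a [kinematic_track()] at `target_fs`.
#' @export
resample_kinematics <- function(track, target_fs, n_out = NULL) {
  stopifnot(inherits(track, "kinematic_track"))
  n_in <- nrow(track$angles)
  if (n_in == 0) stop_fmt("cannot resample an empty track")
  if (target_fs <= 0) stop_fmt("target_fs must be positive")
  t_in <- (seq_len(n_in) - 1) / track$rate
  if (is.null(n_out)) n_out <- ceiling(n_in / track$rate * target_fs)
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- matrix(0, n_out, 16)
  for (j in 1:16) {
    out[, j] <- stats::approx(t_in, track$angles[, j], xout = t_out, rule = 2)$y
  }
  kinematic_track(out, rate = target_fs)
}

#' Median-deviation outlier rejection
#'
#' For every annotated gesture-hold interval, computes the per-joint
#' median over the interval and keeps only the samples whose maximum
#' deviation from those medians (over all joints) is below
#' `max_deviation` degrees. Samples outside any interval are always kept.
#'
#' @param track a [kinematic_track()].
#' @param annotation a [gesture_annotation()]; intervals must lie within
#'   the track.
#' @param max_deviation threshold in degrees (default 15).
#' @return list with `keep` (logical per track sample), `removed_fraction`
#'   (per interval), `overall_removed_fraction`, and `rate` (the track
#'   rate the mask is aligned to).
#' @export
reject_outlier_samples <- function(track, annotation, max_deviation = 15) {
  stopifnot(inherits(track, "kinematic_track"),
            inherits(annotation, "gesture_annotation"))
  if (max_deviation <= 0) stop_fmt("max_deviation must be > 0")
  n <- nrow(track$angles)
  tgrid <- (seq_len(n) - 1) / track$rate
  keep <- rep(TRUE, n)
  removed <- numeric(nrow(annotation))
  n_int_samples <- 0L; n_removed <- 0L
  for (i in seq_len(nrow(annotation))) {
    idx <- which(tgrid >= annotation$onset[i] & tgrid < annotation$offset[i])
    if (!length(idx)) {
      stop_fmt("interval %d (%s, %.2f-%.2f s) contains no kinematic samples",
               i, annotation$label[i], annotation$onset[i], annotation$offset[i])
    }
    seg <- track$angles[idx, , drop = FALSE]
    med <- apply(seg, 2, stats::median)
    dev <- sweep(seg, 2, med)
    maxdev <- apply(abs(dev), 1, max)
    bad <- maxdev >= max_deviation
    keep[idx[bad]] <- FALSE
    removed[i] <- mean(bad)
    n_int_samples <- n_int_samples + length(idx)
    n_removed <- n_removed + sum(bad)
  }
  list(keep = keep,
       removed_fraction = removed,
       overall_removed_fraction = if (n_int_samples) n_removed / n_int_samples else 0,
       rate = track$rate)
}
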