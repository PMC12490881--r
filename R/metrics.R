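#' Normalized joint-angle errors
#'
#' The per-sample, per-joint absolute error between predicted and
#' reference joint angles, divided by each joint's anatomical range of
#' motion (a dimensionless error: 1 means the prediction is off by a full
#' range). Also reports the plain mean absolute error in degrees.
#'
#' @param pred n x 16 predicted angles, degrees.
#' @param truth n x 16 reference angles, degrees.
#' @param ranges per-joint ranges in degrees, see [default_joint_ranges()].
#' @param settings optional per-sample condition labels; when given, the
#'   MAE in degrees is additionally reported per setting.
#' @return list with `normalized` (n x 16), `per_joint` (mean normalized
#'   error per joint), `mae_deg` (overall MAE, degrees), `mae_per_joint`,
#'   and `mae_by_setting` when `settings` is supplied.
#' @export
normalized_joint_error <- function(pred, truth, ranges = default_joint_ranges(),
                                   settings = NULL) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop_fmt("pred and truth must have equal shape")
  if (length(ranges) != ncol(pred)) stop_fmt("need one range per joint")
  if (any(ranges <= 0)) stop_fmt("all joint ranges must be > 0")
  err <- abs(pred - truth)
  norm <- sweep(err, 2, ranges, "/")
  out <- list(normalized = norm,
              per_joint = colMeans(norm),
              mae_deg = mean(err),
              mae_per_joint = colMeans(err))
  if (!is.null(settings)) {
    if (length(settings) != nrow(pred)) stop_fmt("need one setting per sample")
    out$mae_by_setting <- tapply(rowMeans(err), as.character(settings), mean)
  }
  out
}

#' Classification report: confusion matrix, accuracy, per-gesture F1
#'
#' Rows of the confusion matrix are true gestures, columns predictions;
#' accuracy is the trace over the total, and F1 is the per-gesture
#' one-vs-rest harmonic mean of precision and recall (0 when undefined).
#'
#' @param predictions predicted labels.
#' @param truths true labels.
#' @param vocabulary ordered label set; all labels must belong to it.
#' @return list with `confusion`, `accuracy`, `f1` (named per gesture),
#'   `n`.
#' @export
classification_report <- function(predictions, truths,
                                  vocabulary = sort(unique(c(predictions, truths)))) {
  predictions <- as.character(predictions); truths <- as.character(truths)
  if (length(predictions) != length(truths)) stop_fmt("predictions and truths differ in length")
  outside <- setdiff(unique(c(predictions, truths)), vocabulary)
  if (length(outside)) stop_fmt("label(s) outside the vocabulary: %s", paste(outside, collapse = ", "))
  cm <- table(factor(truths, levels = vocabulary),
              factor(predictions, levels = vocabulary))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "prediction")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(f1) <- vocabulary
  list(confusion = cm,
       accuracy = sum(tp) / sum(cm),
       f1 = f1,
       n = length(truths))
}

#' Pearson correlation between per-setting accuracy profiles
#'
#' Given a subjects x settings matrix of accuracies, returns the
#' settings x settings Pearson correlation matrix of the per-subject
#' accuracy vectors (how similarly subjects rank across conditions).
#'
#' @param per_subject_accuracy numeric matrix, subjects in rows, settings
#'   in columns.
#' @return settings x settings correlation matrix (unit diagonal).
#' @export
setting_correlation <- function(per_subject_accuracy) {
  m <- as.matrix(per_subject_accuracy)
  if (nrow(m) < 3) stop_fmt("need at least 3 subjects for a meaningful correlation, got %d", nrow(m))
  r <- stats::cor(m, method = "pearson")
  diag(r) <- 1
  # snap floating-point residue so duplicated (or exactly negated)
  # columns report +/-1 exactly
  r[abs(r - 1) < 1e-12] <- 1
  r[abs(r + 1) < 1e-12] <- -1
  r
}

#' Paired t-test on per-subject accuracies
#'
#' Two-sided paired t-test of the difference between two matched accuracy
#' vectors. Zero-variance differences are degenerate for the t statistic;
#' they are returned flagged (`degenerate = TRUE`) with `t = 0, p = 1`
#' for identical vectors and `t = +/-Inf, p = 0` for a constant nonzero
#' shift, rather than erroring.
#'
#' @param acc_a,acc_b equal-length numeric vectors.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop_fmt("paired vectors must have equal length")
  if (length(acc_a) < 2) stop_fmt("need at least 2 pairs")
  d <- acc_a - acc_b
  if (stats::sd(d) < .Machine$double.eps * max(1, abs(mean(d)))) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                df = length(d) - 1, mean_diff = md, degenerate = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Inter-onset-interval analysis
#'
#' Successive differences of gesture onset times, compared with the ideal
#' cue cycle (hold plus pause, 8 s by default): the empirical CDF of the
#' intervals and the mean absolute deviation from the ideal cycle.
#'
#' @param onsets gesture onset times in seconds (one session, sorted).
#' @param ideal_cycle ideal onset-to-onset interval, seconds.
#' @return list with `ioi` (intervals), `cdf` (ecdf function),
#'   `mean_abs_deviation`, `ideal_cycle`.
#' @export
ioi_analysis <- function(onsets, ideal_cycle = 8) {
  onsets <- sort(as.numeric(onsets))
  if (length(onsets) < 2) stop_fmt("need at least 2 onsets for inter-onset intervals")
  ioi <- diff(onsets)
  list(ioi = ioi,
       cdf = stats::ecdf(ioi),
       mean_abs_deviation = mean(abs(ioi - ideal_cycle)),
       ideal_cycle = ideal_cycle)
}

#' Classical EMG time/frequency features of a signal segment
#'
#' Zero crossings (strict sign changes whose step exceeds a dead-band),
#' slope sign changes (sign changes of the first difference, same
#' dead-band), and the central frequency (power-spectral centroid of a
#' Hann-tapered periodogram restricted to `band`).
#'
#' @param x numeric signal segment (z-scored sEMG units).
#' @param fs sampling rate, Hz.
#' @param deadband amplitude threshold below which a change is ignored.
#' @param band Hz interval over which the spectral centroid is taken.
#' @return list with `zero_crossings`, `slope_sign_changes`,
#'   `central_frequency`.
#' @export
signal_features <- function(x, fs, deadband = 0.01, band = c(20, 450)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop_fmt("segment must have at least 2 samples")
  zc <- sum(x[-n] * x[-1] < 0 & abs(x[-1] - x[-n]) > deadband)
  dx <- diff(x)
  ssc <- if (n >= 3) {
    sum(dx[-(n - 1)] * dx[-1] < 0 &
          (abs(dx[-(n - 1)]) > deadband | abs(dx[-1]) > deadband))
  } else 0
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xs <- (x - mean(x)) * w
  sp <- abs(stats::fft(xs))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  inband <- half & freqs >= band[1] & freqs <= min(band[2], fs / 2)
  cf <- if (any(inband) && sum(sp[inband]) > 0) {
    sum(freqs[inband] * sp[inband]) / sum(sp[inband])
  } else NA_real_
  list(zero_crossings = zc, slope_sign_changes = ssc, central_frequency = cf)
}

#' Signal-feature table over windows of a recording
#'
#' Applies [signal_features()] per channel over consecutive
#' non-overlapping windows and summarizes: mean zero crossings and slope
#' sign changes per window, and the variance of the central frequency
#' across windows (an index of spectral nonstationarity).
#'
#' @param recording an [semg_recording()] (typically filtered/z-scored).
#' @param window_s window length in seconds.
#' @param deadband see [signal_features()].
#' @param band see [signal_features()].
#' @return data.frame, one row per channel: mean `zero_crossings` and
#'   `slope_sign_changes`, `central_frequency` mean and
#'   `central_frequency_variance`, `n_windows`.
#' @export
signal_feature_table <- function(recording, window_s = 0.512,
                                 deadband = 0.01, band = c(20, 450)) {
  stopifnot(inherits(recording, "semg_recording"))
  S <- round(window_s * recording$fs)
  n <- nrow(recording$samples)
  nw <- n %/% S
  if (nw < 1) stop_fmt("recording shorter than one window")
  out <- lapply(seq_len(ncol(recording$samples)), function(ch) {
    feats <- vapply(seq_len(nw), function(k) {
      seg <- recording$samples[((k - 1) * S + 1):(k * S), ch]
      f <- signal_features(seg, recording$fs, deadband, band)
      c(f$zero_crossings, f$slope_sign_changes, f$central_frequency)
    }, numeric(3))
    data.frame(channel = recording$channel_ids[ch],
               zero_crossings = mean(feats[1, ]),
               slope_sign_changes = mean(feats[2, ]),
               central_frequency = mean(feats[3, ], na.rm = TRUE),
               central_frequency_variance = stats::var(feats[3, ], na.rm = TRUE),
               n_windows = nw, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
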