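#' Windowing configuration
#'
#' @param window_ms rolling window length, milliseconds (default 512).
#' @param stride_ms stride between consecutive window starts (default 2).
#' @param grid_shape electrode grid width x height (fixed 4 x 4).
#' @return a `windowing_config`.
#' @export
windowing_config <- function(window_ms = 512, stride_ms = 2, grid_shape = c(4, 4)) {
  if (!(window_ms > stride_ms && stride_ms > 0)) {
    stop_fmt("need window_ms > stride_ms > 0 (got %g, %g)", window_ms, stride_ms)
  }
  if (!identical(as.integer(grid_shape), c(4L, 4L))) stop_fmt("grid_shape must be 4 x 4")
  structure(list(window_ms = window_ms, stride_ms = stride_ms,
                 grid_shape = c(4L, 4L)),
            class = "windowing_config")
}

#' Segment a recording into rolling windows
#'
#' Computes the window plan for a rolling-window segmentation: with N
#' input samples, S samples per window and stride t, there are
#' L = floor((N - S) / t) + 1 windows and window k starts at sample
#' (k - 1) * t + 1. The plan holds start indices plus a reference to the
#' recording; tensors are materialized by [to_grid()], so very long
#' low-stride segmentations stay cheap until windows are actually needed.
#'
#' @param recording an [semg_recording()].
#' @param config a [windowing_config()].
#' @return an `semg_windows` plan with elements `starts` (1-based start
#'   samples), `window_samples`, `stride_samples`, `fs`, `recording`.
#' @export
segment_windows <- function(recording, config = windowing_config()) {
  stopifnot(inherits(recording, "semg_recording"))
  fs <- recording$fs
  S <- as.integer(round(config$window_ms * fs / 1000))
  t <- as.integer(round(config$stride_ms * fs / 1000))
  if (t < 1) stop_fmt("stride of %g ms is below one sample at fs %g", config$stride_ms, fs)
  N <- nrow(recording$samples)
  if (N < S) {
    stop_fmt("recording has %d samples but one %g ms window needs %d", N, config$window_ms, S)
  }
  L <- floor((N - S) / t) + 1
  starts <- (seq_len(L) - 1L) * t + 1L
  structure(list(starts = starts, window_samples = S,
                 stride_samples = t, fs = fs,
                 recording = recording),
            class = "semg_windows")
}

#' @export
print.semg_windows <- function(x, ...) {
  cat(sprintf("<semg_windows> %d windows of %d samples (stride %d) @ %g Hz\n",
              length(x$starts), x$window_samples, x$stride_samples, x$fs))
  invisible(x)
}

#' Materialize windows as a grid video tensor
#'
#' Maps every window onto the electrode grid: the result is a 4-D array
#' `[L windows x S samples x 4 x 4]` where channel c occupies the grid
#' cell given by the recording's layout. The inverse map (reading cells
#' back in layout order) recovers the channel-major windows exactly.
#'
#' @param windows an `semg_windows` plan from [segment_windows()].
#' @param layout optional layout override (defaults to the recording's).
#' @param which optional integer subset of windows to materialize.
#' @return a `window_tensor` with `data` (L x S x 4 x 4), `window_times`
#'   (window end times, seconds), `starts`, `fs`; targets and labels are
#'   attached by [assign_targets()].
#' @export
to_grid <- function(windows, layout = NULL, which = NULL) {
  stopifnot(inherits(windows, "semg_windows"))
  rec <- windows$recording
  if (is.null(layout)) layout <- rec$grid_layout
  check_grid_layout(layout, rec$channel_ids)
  starts <- windows$starts
  if (!is.null(which)) starts <- starts[which]
  S <- windows$window_samples
  L <- length(starts)
  x <- array(0, dim = c(L, S, 4, 4))
  # cell index (row, col) for each channel, in the channel order of samples
  pos <- layout[match(rec$channel_ids, layout$channel), ]
  for (ch in 1:16) {
    col_v <- rec$samples[, ch]
    # windows x samples slab for this channel
    idx <- outer(starts, 0:(S - 1), "+")
    x[, , pos$row[ch], pos$col[ch]] <- col_v[idx]
  }
  structure(list(data = x,
                 window_times = (starts + S - 1 - 1) / windows$fs,
                 starts = starts,
                 window_samples = S, stride_samples = windows$stride_samples,
                 fs = windows$fs, layout = layout,
                 channel_ids = rec$channel_ids,
                 targets = NULL, labels = NULL),
            class = "window_tensor")
}

#' @export
print.window_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<window_tensor> %d windows x %d samples x %dx%d grid%s\n",
              d[1], d[2], d[3], d[4],
              if (is.null(x$targets)) "" else " (+targets)"))
  invisible(x)
}

#' Recover channel-major windows from a grid tensor
#'
#' @param tensor a `window_tensor`.
#' @return array L x S x 16 in the original channel order.
#' @export
from_grid <- function(tensor) {
  stopifnot(inherits(tensor, "window_tensor"))
  d <- dim(tensor$data)
  out <- array(0, dim = c(d[1], d[2], 16))
  pos <- tensor$layout[match(tensor$channel_ids, tensor$layout$channel), ]
  for (ch in 1:16) out[, , ch] <- tensor$data[, , pos$row[ch], pos$col[ch]]
  out
}

#' Attach per-window kinematic targets and gesture labels
#'
#' Pairs every window with a 16-joint angle target read from a kinematic
#' track resampled onto the sEMG clock, under one of three reduction
#' policies: the angle at the window end (default; causal prediction of
#' the current pose), at the window center, or the mean over the window.
#' Each window also receives the gesture label of the annotated event
#' covering its target time, or `"rest"`. Windows that overlap samples
#' flagged by the outlier mask are dropped.
#'
#' @param tensor a `window_tensor` from [to_grid()].
#' @param kinematics a [kinematic_track()] resampled to the sEMG rate.
#' @param annotation a [gesture_annotation()].
#' @param policy one of `"end"`, `"center"`, `"mean"`.
#' @param outlier_mask optional result of [reject_outlier_samples()]
#'   computed on `kinematics` (same rate); offending windows are removed.
#' @return the tensor with `targets` (L x 16), `labels`, `repetition`
#'   filled in (possibly fewer windows).
#' @export
assign_targets <- function(tensor, kinematics, annotation,
                           policy = c("end", "center", "mean"),
                           outlier_mask = NULL) {
  stopifnot(inherits(tensor, "window_tensor"),
            inherits(kinematics, "kinematic_track"),
            inherits(annotation, "gesture_annotation"))
  policy <- match.arg(policy)
  if (abs(kinematics$rate - tensor$fs) > 1e-6) {
    stop_fmt("kinematics are at %g Hz but windows are on a %g Hz clock; resample_kinematics() first",
             kinematics$rate, tensor$fs)
  }
  S <- tensor$window_samples
  starts <- tensor$starts
  ends <- starts + S - 1L
  nk <- nrow(kinematics$angles)
  if (max(ends) > nk) {
    stop_fmt("kinematic track (%d samples) is shorter than the windowed span (%d)", nk, max(ends))
  }
  keep <- rep(TRUE, length(starts))
  if (!is.null(outlier_mask)) {
    if (abs(outlier_mask$rate - tensor$fs) > 1e-6) {
      stop_fmt("outlier mask is on a %g Hz clock, windows on %g Hz", outlier_mask$rate, tensor$fs)
    }
    bad <- which(!outlier_mask$keep)
    if (length(bad)) {
      # a window is dropped if any of its samples is flagged
      bad_cum <- cumsum(tabulate(bad, nbins = nk))
      n_bad_in <- bad_cum[ends] - c(0, bad_cum)[starts]
      keep <- n_bad_in == 0
    }
  }
  tgt_idx <- switch(policy, end = ends, center = starts + (S %/% 2),
                    mean = NULL)
  if (policy == "mean") {
    tg <- t(vapply(seq_along(starts), function(i) {
      colMeans(kinematics$angles[starts[i]:ends[i], , drop = FALSE])
    }, numeric(16)))
    t_time <- (starts + ends) / 2 / tensor$fs
  } else {
    tg <- kinematics$angles[tgt_idx, , drop = FALSE]
    t_time <- (tgt_idx - 1) / tensor$fs
  }
  lab <- rep("rest", length(starts))
  rep_idx <- rep(NA_integer_, length(starts))
  ev_idx <- rep(NA_integer_, length(starts))
  ev <- findInterval(t_time, annotation$onset)
  inside <- ev >= 1 & ev <= nrow(annotation) &
    t_time < annotation$offset[pmax(ev, 1)]
  lab[inside] <- annotation$label[ev[inside]]
  rep_idx[inside] <- annotation$repetition[ev[inside]]
  ev_idx[inside] <- ev[inside]
  out <- tensor
  out$data <- tensor$data[keep, , , , drop = FALSE]
  out$starts <- starts[keep]
  out$window_times <- tensor$window_times[keep]
  out$targets <- tg[keep, , drop = FALSE]
  colnames(out$targets) <- joint_names()
  out$labels <- lab[keep]
  out$repetition <- rep_idx[keep]
  out$event <- ev_idx[keep]
  out$target_policy <- policy
  out
}

#' Subset a window tensor
#'
#' @param tensor a `window_tensor`.
#' @param idx integer or logical window index.
#' @return the tensor restricted to the selected windows.
#' @export
subset_windows <- function(tensor, idx) {
  stopifnot(inherits(tensor, "window_tensor"))
  out <- tensor
  out$data <- tensor$data[idx, , , , drop = FALSE]
  out$starts <- tensor$starts[idx]
  out$window_times <- tensor$window_times[idx]
  for (f in c("labels", "repetition", "event")) {
    if (!is.null(tensor[[f]])) out[[f]] <- tensor[[f]][idx]
  }
  if (!is.null(tensor$targets)) out$targets <- tensor$targets[idx, , drop = FALSE]
  out
}

#' Augmentation configuration
#'
#' Training-time augmentation for z-scored window tensors: each channel is
#' independently silenced with probability `silence_prob` for one span of
#' duration uniform on `silence_duration` milliseconds, then i.i.d.
#' Gaussian noise of SD `noise_sd` is added to all samples.
#'
#' @param silence_prob per-channel silencing probability.
#' @param silence_duration two-element ms interval for the span duration.
#' @param noise_sd Gaussian noise SD (on z-scored signal units).
#' @param scale_sd lognormal SD of an optional per-window global amplitude
#'   jitter (all channels scaled by one factor, applied before silencing):
#'   emulates contraction-force variability and teaches the decoder scale
#'   invariance. 0 (the default) disables it.
#' @param seed RNG seed.
#' @return an `augment_config`.
#' @export
augment_config <- function(silence_prob = 0.5, silence_duration = c(6, 400),
                           noise_sd = 0.1, scale_sd = 0, seed = 1L) {
  if (silence_prob < 0 || silence_prob > 1) stop_fmt("silence_prob must be in [0, 1]")
  if (length(silence_duration) != 2 || silence_duration[1] <= 0 ||
      silence_duration[2] < silence_duration[1]) {
    stop_fmt("silence_duration must be a positive ordered ms interval")
  }
  if (noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  if (scale_sd < 0) stop_fmt("scale_sd must be >= 0")
  structure(list(silence_prob = silence_prob, silence_duration = silence_duration,
                 noise_sd = noise_sd, scale_sd = scale_sd, seed = as.integer(seed)),
            class = "augment_config")
}

#' Augment a window tensor (training only)
#'
#' Silencing draws, for each selected (window, channel) pair, one span
#' whose duration is uniform on the configured millisecond interval and
#' whose onset is uniform among positions where the span fits in the
#' window; the span is set to exactly zero. A span longer than the window
#' is truncated to the window with a warning. Gaussian noise is then
#' added to every sample. Fully seeded and reproducible; the returned
#' tensor carries a `silence_log` attribute recording every drawn span.
#'
#' @param tensor a `window_tensor` (or a plain L x S x 4 x 4 array).
#' @param config an [augment_config()].
#' @param fs sampling rate; taken from the tensor when present.
#' @return augmented tensor of identical shape.
#' @export
augment_windows <- function(tensor, config = augment_config(), fs = NULL) {
  is_wt <- inherits(tensor, "window_tensor")
  x <- if (is_wt) tensor$data else tensor
  if (length(dim(x)) != 4) stop_fmt("expected an L x S x W x H array")
  if (is.null(fs)) {
    if (!is_wt) stop_fmt("fs is required for a bare array")
    fs <- tensor$fs
  }
  d <- dim(x)
  L <- d[1]; S <- d[2]
  log_rows <- list()
  x <- with_seed(config$seed, {
    if (config$scale_sd > 0) {
      sc <- stats::rlnorm(L, meanlog = -config$scale_sd^2 / 2, sdlog = config$scale_sd)
      x <- x * sc   # L is the fastest-varying dimension: one factor per window
    }
    if (config$silence_prob > 0) {
      warned <- FALSE
      for (l in seq_len(L)) {
        for (r in seq_len(d[3])) for (cc in seq_len(d[4])) {
          if (stats::runif(1) >= config$silence_prob) next
          dur_ms <- stats::runif(1, config$silence_duration[1], config$silence_duration[2])
          dur <- max(1L, round(dur_ms * fs / 1000))
          if (dur > S) {
            if (!warned) {
              warning(sprintf("silence span (%.0f ms) exceeds the window; truncating", dur_ms))
              warned <- TRUE
            }
            dur <- S
          }
          onset <- sample.int(S - dur + 1L, 1L)
          x[l, onset:(onset + dur - 1L), r, cc] <- 0
          log_rows[[length(log_rows) + 1L]] <- c(l, r, cc, onset, dur)
        }
      }
    }
    if (config$noise_sd > 0) {
      x <- x + array(stats::rnorm(length(x), 0, config$noise_sd), dim = d)
    }
    x
  })
  log_df <- if (length(log_rows)) {
    m <- do.call(rbind, log_rows)
    data.frame(window = m[, 1], row = m[, 2], col = m[, 3],
               onset = m[, 4], duration_samples = m[, 5],
               duration_ms = m[, 5] / fs * 1000)
  } else {
    data.frame(window = integer(), row = integer(), col = integer(),
               onset = integer(), duration_samples = integer(),
               duration_ms = numeric())
  }
  if (is_wt) {
    tensor$data <- x
    attr(tensor, "silence_log") <- log_df
    tensor
  } else {
    attr(x, "silence_log") <- log_df
    x
  }
}
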