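test_that("a constant-offset input is annihilated by the high-pass", {
  x <- matrix(3.7, 4000, 16)
  out <- filter_semg(semg_recording(x, fs = 1000), preprocess_config(zscore = FALSE))
  # the DC component is removed to well below 1% once edge transients settle
  expect_lt(max(abs(out$samples[500:3500, ])), 0.01 * 3.7)
})

test_that("50 and 100 Hz tones are suppressed to below 1% RMS", {
  expect_lt(tone_gain(50), 0.01)
  expect_lt(tone_gain(100), 0.01)
})

test_that("high-pass gain at the 20 Hz cutoff matches the analytic Butterworth response", {
  g <- tone_gain(20)
  # |H|^2 at cutoff for a 4th-order Butterworth applied forward-backward
  analytic <- 0.5
  expect_lt(abs(20 * log10(g) - 20 * log10(analytic)), 0.5)
})

test_that("a 150 Hz tone passes with near-unity gain", {
  expect_equal(tone_gain(150), 1, tolerance = 0.05)
})

test_that("comb harmonics are optional and notch every multiple when enabled", {
  cfg <- preprocess_config(comb_harmonics = TRUE, zscore = FALSE)
  expect_lt(tone_gain(150, config = cfg), 0.01)
  expect_lt(tone_gain(200, config = cfg), 0.01)
})

test_that("z-scored channels have mean 0 and unit SD, and z-scoring is idempotent", {
  s <- tiny_session(seed = 41)
  out <- filter_semg(s$semg, preprocess_config())
  expect_true(all(abs(colMeans(out$samples)) < 1e-9))
  expect_true(all(abs(apply(out$samples, 2, sd) - 1) < 1e-9))
  # a second z-score pass (no further filtering) leaves the signal unchanged
  mu <- colMeans(out$samples); sdv <- apply(out$samples, 2, sd)
  again <- sweep(sweep(out$samples, 2, mu), 2, sdv, "/")
  expect_equal(again, out$samples, tolerance = 1e-12)
})

test_that("constant channels fall back to zeros with a warning under z-score", {
  x <- matrix(rnorm(16000), 1000, 16)
  x[, 3] <- 0
  expect_warning(out <- filter_semg(semg_recording(x, fs = 1000), preprocess_config()),
                 "constant")
  expect_true(all(out$samples[, 3] == 0))
})

test_that("pre-normalization filtering is linear", {
  set.seed(7)
  cfg <- preprocess_config(zscore = FALSE)
  x <- matrix(rnorm(16 * 2000), 2000, 16)
  y <- matrix(rnorm(16 * 2000), 2000, 16)
  fx <- filter_semg(semg_recording(x, fs = 1000), cfg)$samples
  fy <- filter_semg(semg_recording(y, fs = 1000), cfg)$samples
  fxy <- filter_semg(semg_recording(2 * x - 3 * y, fs = 1000), cfg)$samples
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)
})

test_that("non-finite input is rejected", {
  x <- matrix(0, 100, 16); x[5, 2] <- NA
  expect_error(filter_semg(semg_recording(x, fs = 1000)), "non-finite")
})

test_that("Savitzky-Golay smoothing preserves constants and interior ramps", {
  n <- 2000
  cfg <- preprocess_config(savgol_window = 101)
  const <- kinematic_track(matrix(12, n, 16), rate = 120)
  expect_equal(smooth_kinematics(const, cfg)$angles, const$angles, tolerance = 1e-10)
  ramp <- kinematic_track(matrix(seq_len(n), n, 16), rate = 120)
  sm <- smooth_kinematics(ramp, cfg)$angles
  interior <- 101:(n - 101)
  expect_equal(sm[interior, 1], as.numeric(interior), tolerance = 1e-8)
})

test_that("order-1 smoothing attenuates white noise like a moving average", {
  set.seed(11)
  n <- 60000
  x <- matrix(rnorm(n * 16, sd = 3), n, 16)
  sm <- smooth_kinematics(kinematic_track(x, rate = 120),
                          preprocess_config(savgol_window = 502))$angles
  interior <- 1000:(n - 1000)
  # an order-1 fit over a symmetric 501-sample window is its mean
  expect_equal(sd(sm[interior, 1]), 3 / sqrt(501), tolerance = 0.1)
})

test_that("tracks shorter than the smoothing window are rejected with advice", {
  tr <- kinematic_track(matrix(0, 100, 16), rate = 120)
  expect_error(smooth_kinematics(tr, preprocess_config(savgol_window = 502)),
               "smaller savgol_window")
})

test_that("resampling holds constants, preserves ramps, and is accurate on smooth tracks", {
  const <- kinematic_track(matrix(5, 120, 16), rate = 120)
  up <- resample_kinematics(const, 4000)
  expect_true(all(up$angles == 5))
  expect_equal(up$rate, 4000)

  ramp <- kinematic_track(matrix(seq(0, 90, length.out = 120), 120, 16), rate = 120)
  up <- resample_kinematics(ramp, 4000)
  t_out <- (seq_len(nrow(up$angles)) - 1) / 4000
  t_last <- 119 / 120
  expect_equal(up$angles[, 1], 90 * pmin(t_out, t_last) / t_last, tolerance = 1e-9)

  # band-limited track: down/up round trip stays within the linear
  # interpolation error bound  max|f''| h^2 / 8
  t_hi <- seq(0, 2, by = 1 / 1200)
  f <- 4
  x <- matrix(40 * sin(2 * pi * f * t_hi), ncol = 1)[, rep(1, 16)]
  tr <- kinematic_track(x, rate = 1200)
  down <- resample_kinematics(tr, 120)
  back <- resample_kinematics(down, 1200, n_out = nrow(x))
  bound <- 40 * (2 * pi * f)^2 * (1 / 120)^2 / 8
  expect_lt(max(abs(back$angles[, 1] - x[, 1])), bound * 1.05)
})

test_that("the 15-degree median-deviation rule matches the worked example", {
  n <- 3
  ang <- matrix(20, n, 16)
  ang[, 5] <- c(10, 12, 40)
  tr <- kinematic_track(ang, rate = 1)
  ann <- gesture_annotation(data.frame(label = "fist", onset = 0, offset = 3,
                                       repetition = 1L, setting = "static1"))
  res <- reject_outlier_samples(tr, ann, max_deviation = 15)
  expect_equal(res$keep, c(TRUE, TRUE, FALSE))
  expect_equal(res$removed_fraction, 1 / 3)
  expect_equal(res$overall_removed_fraction, 1 / 3)
})

test_that("outlier rule keeps everything for tight tracks and infinite thresholds", {
  set.seed(3)
  ang <- matrix(30, 50, 16) + matrix(runif(50 * 16, -0.5, 0.5), 50, 16)
  tr <- kinematic_track(ang, rate = 10)
  ann <- gesture_annotation(data.frame(label = "fist", onset = 0, offset = 5,
                                       repetition = 1L, setting = "static1"))
  expect_true(all(reject_outlier_samples(tr, ann, 15)$keep))
  ang[7, 2] <- 500
  tr2 <- kinematic_track(ang, rate = 10)
  expect_false(all(reject_outlier_samples(tr2, ann, 15)$keep))
  expect_true(all(reject_outlier_samples(tr2, ann, Inf)$keep))
})

test_that("outlier rule agrees with a brute-force re-implementation", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 40
    ang <- matrix(rnorm(n * 16, 45, 8), n, 16)
    tr <- kinematic_track(ang, rate = 20)
    ann <- gesture_annotation(data.frame(label = c("a", "b"),
                                         onset = c(0.1, 1.0), offset = c(0.9, 1.9),
                                         repetition = c(1L, 1L), setting = "static1"))
    thr <- runif(1, 5, 20)
    res <- reject_outlier_samples(tr, ann, thr)
    keep_bf <- rep(TRUE, n)
    tgrid <- (seq_len(n) - 1) / 20
    for (i in 1:2) {
      idx <- which(tgrid >= ann$onset[i] & tgrid < ann$offset[i])
      med <- apply(ang[idx, ], 2, median)
      for (k in idx) {
        if (max(abs(ang[k, ] - med)) >= thr) keep_bf[k] <- FALSE
      }
    }
    expect_equal(res$keep, keep_bf)
  }
})

test_that("removed fraction is monotone non-increasing in the threshold", {
  set.seed(23)
  ang <- matrix(rnorm(200 * 16, 45, 10), 200, 16)
  tr <- kinematic_track(ang, rate = 20)
  ann <- gesture_annotation(data.frame(label = "a", onset = 0, offset = 10,
                                       repetition = 1L, setting = "static1"))
  fr <- vapply(c(2, 5, 10, 15, 25, 50),
               function(d) reject_outlier_samples(tr, ann, d)$overall_removed_fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})
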