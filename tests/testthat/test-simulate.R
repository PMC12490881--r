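test_that("default templates are complete and electromyographically distinct", {
  tmpl <- gesture_templates()
  expect_equal(dim(tmpl$angles), c(14, 16))
  expect_equal(dim(tmpl$gains), c(14, 16))
  expect_true(all(tmpl$gains >= 0))
  # every pair of gestures must differ both in pose and activation pattern
  gn <- tmpl$gains / sqrt(rowSums(tmpl$gains^2))
  dg <- as.matrix(dist(gn)); diag(dg) <- Inf
  expect_gt(min(dg), 0.2)
  da <- as.matrix(dist(tmpl$angles)); diag(da) <- Inf
  expect_gt(min(da), 10)
})

test_that("noiseless kinematics sit exactly on the template plateau and rest pose", {
  tmpl <- tiny_templates(angle_noise_sd = 0)
  ann <- make_protocol(tiny_protocol())
  kin <- synth_kinematics(ann, tmpl, rate = 100, seed = 1)
  tgrid <- (seq_len(nrow(kin$angles)) - 1) / 100
  for (i in c(1, nrow(ann))) {
    mid <- (ann$onset[i] + ann$offset[i]) / 2
    k <- which.min(abs(tgrid - mid))
    expect_equal(unname(kin$angles[k, ]), unname(tmpl$angles[ann$label[i], ]))
  }
  pause_mid <- ann$offset[1] + 0.25   # 0.3 s pause, transition 0.1 s
  k <- which.min(abs(tgrid - pause_mid))
  expect_equal(unname(kin$angles[k, ]), unname(tmpl$rest_pose))
})

test_that("estimator noise has the configured standard deviation", {
  tmpl <- gesture_templates(angle_noise_sd = 2)
  ann <- gesture_annotation(data.frame(label = "fist", onset = 1, offset = 30,
                                       repetition = 1L, setting = "static1"))
  kin <- synth_kinematics(ann, tmpl, rate = 120, seed = 9)
  tgrid <- (seq_len(nrow(kin$angles)) - 1) / 120
  plateau <- tgrid > 2 & tgrid < 29   # > 1000 samples well inside the hold
  dev <- sweep(kin$angles[plateau, ], 2, tmpl$angles["fist", ])
  expect_lt(abs(sd(as.numeric(dev)) - 2) / 2, 0.1)
})

test_that("missing gesture templates are reported by label", {
  tmpl <- tiny_templates(2)
  ann <- make_protocol(tiny_protocol(3))
  expect_error(synth_kinematics(ann, tmpl, rate = 50), "index_point")
  expect_error(synth_semg(ann, tmpl, tiny_noise(), fs = 200), "index_point")
})

test_that("silent gains, zero noise and no line terms give an all-zero signal", {
  tmpl <- tiny_templates(gains = matrix(0, 3, 16))
  ann <- make_protocol(tiny_protocol())
  rec <- synth_semg(ann, tmpl,
                    noise_model(carrier_band = c(20, 80), line_amps = c(0, 0),
                                baseline_sd = 0, artifact_rate = 0),
                    fs = 200, seed = 2)
  expect_true(all(rec$samples == 0))
})

test_that("hold-period RMS exceeds pause-period RMS on active channels", {
  tmpl <- tiny_templates()
  ann <- make_protocol(tiny_protocol())
  rec <- synth_semg(ann, tmpl,
                    noise_model(carrier_band = c(20, 80), line_amps = c(0, 0),
                                baseline_sd = 0.5, artifact_rate = 0),
                    fs = 200, seed = 3)
  tgrid <- (seq_len(nrow(rec$samples)) - 1) / 200
  i <- 2
  lab <- ann$label[i]
  hold <- tgrid >= ann$onset[i] + 0.2 & tgrid < ann$offset[i]
  pause <- tgrid >= ann$offset[i] + 0.2 & tgrid < ann$offset[i] + 0.28
  for (ch in which(tmpl$gains[lab, ] > 5)) {
    expect_gt(sqrt(mean(rec$samples[hold, ch]^2)),
              sqrt(mean(rec$samples[pause, ch]^2)))
  }
})

test_that("line interference produces a spectral peak of the configured amplitude", {
  tmpl <- tiny_templates(gains = matrix(0, 3, 16))
  ann <- make_protocol(tiny_protocol())
  a <- 7.5
  rec <- synth_semg(ann, tmpl,
                    noise_model(carrier_band = c(20, 80), line_freqs = 50,
                                line_amps = a, baseline_sd = 0, artifact_rate = 0),
                    fs = 400, duration = 10, seed = 4)
  x <- rec$samples[1:4000, 1]
  n <- length(x)
  amp <- 2 * Mod(stats::fft(x)) / n
  freqs <- (seq_len(n) - 1) * 400 / n
  idx <- which(freqs > 0 & freqs < 200)
  k <- idx[which.max(amp[idx])]
  expect_equal(freqs[k], 50, tolerance = 0.2)
  expect_equal(amp[k], a, tolerance = 0.01 * a)
})

test_that("sampling rate must exceed twice the carrier-band top", {
  tmpl <- tiny_templates()
  ann <- make_protocol(tiny_protocol())
  expect_error(synth_semg(ann, tmpl, noise_model(carrier_band = c(20, 450)),
                          fs = 800), "twice the carrier band")
})

test_that("sEMG envelope onset lags the kinematic onset by the configured lag", {
  lag <- 0.15
  tmpl <- gesture_templates(gestures = default_gestures(3),
                            transition_time = 0.1, angle_noise_sd = 0,
                            onset_lag = lag, force_variability_cv = 0)
  ann <- make_protocol(tiny_protocol(hold = 1.5, pause = 1))
  fs <- 500
  rec <- synth_semg(ann, tmpl,
                    noise_model(carrier_band = c(20, 120), line_amps = c(0, 0),
                                baseline_sd = 0, artifact_rate = 0),
                    fs = fs, seed = 6)
  i <- 3
  ch <- which.max(tmpl$gains[ann$label[i], ])
  tgrid <- (seq_len(nrow(rec$samples)) - 1) / fs
  first_active <- tgrid[which(abs(rec$samples[, ch]) > 0 &
                                tgrid >= ann$onset[i] - 0.5)[1]]
  expect_equal(first_active, ann$onset[i] + lag, tolerance = 2 / fs)
})

test_that("sessions are bit-identical under the same seed", {
  s1 <- tiny_session(seed = 21)
  s2 <- tiny_session(seed = 21)
  s3 <- tiny_session(seed = 22)
  expect_identical(s1$semg$samples, s2$semg$samples)
  expect_identical(s1$kinematics$angles, s2$kinematics$angles)
  expect_identical(s1$annotation, s2$annotation)
  expect_false(identical(s1$semg$samples, s3$semg$samples))
})

test_that("session duration covers the full protocol schedule", {
  s <- tiny_session(seed = 5)
  cfg <- tiny_protocol()
  expect_gte(nrow(s$semg$samples), protocol_duration(cfg) * s$semg$fs - 1)
  expect_equal(nrow(s$annotation), cfg$n_gestures * cfg$n_repetitions)
})
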