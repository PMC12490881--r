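test_that("window counts follow the rolling-window formula", {
  rec <- semg_recording(matrix(rnorm(4096 * 16), 4096, 16), fs = 4000)
  w <- segment_windows(rec, windowing_config(512, 2))
  expect_equal(length(w$starts), (4096 - 2048) / 8 + 1)   # 257
  expect_equal(w$window_samples, 2048)
  expect_equal(w$stride_samples, 8)

  one <- semg_recording(matrix(rnorm(2048 * 16), 2048, 16), fs = 4000)
  expect_equal(length(segment_windows(one, windowing_config(512, 2))$starts), 1)

  short <- semg_recording(matrix(rnorm(2047 * 16), 2047, 16), fs = 4000)
  expect_error(segment_windows(short, windowing_config(512, 2)), "needs")
})

test_that("window count and start indices match brute-force enumeration", {
  set.seed(77)
  for (k in 1:100) {
    S <- sample(8:64, 1)
    t <- sample(1:(S - 1), 1)
    N <- S + sample(0:300, 1)
    rec <- semg_recording(matrix(0, N, 16), fs = 1000)
    cfg <- windowing_config(window_ms = S, stride_ms = t)  # 1 kHz: ms == samples
    w <- segment_windows(rec, cfg)
    brute <- integer(0)
    s0 <- 1L
    while (s0 + S - 1 <= N) { brute <- c(brute, s0); s0 <- s0 + t }
    expect_equal(w$starts, brute)
    expect_equal(length(w$starts), floor((N - S) / t) + 1)
  }
})

test_that("grid mapping honors the layout and round-trips exactly", {
  set.seed(5)
  N <- 300
  x <- matrix(rnorm(N * 16), N, 16)
  rec <- semg_recording(x, fs = 1000)
  w <- segment_windows(rec, windowing_config(64, 16))
  g <- to_grid(w)
  # identity (row-major) layout: data[l, s, r, c] = window[l, s, 4(r-1)+c]
  for (l in c(1, length(w$starts))) for (ch in c(1, 7, 16)) {
    r <- (ch - 1) %/% 4 + 1; cc <- (ch - 1) %% 4 + 1
    expect_equal(g$data[l, , r, cc], x[w$starts[l]:(w$starts[l] + 63), ch])
  }
  expect_equal(from_grid(g)[1, , ], x[1:64, ])

  # a permuted layout moves channels to exactly the permuted cells
  perm <- sample(16)
  layout2 <- default_grid_layout()
  layout2$channel <- layout2$channel[perm]
  g2 <- to_grid(w, layout = layout2)
  pos <- layout2[match(rec$channel_ids, layout2$channel), ]
  for (ch in c(2, 9)) {
    expect_equal(g2$data[1, , pos$row[ch], pos$col[ch]], x[1:64, ch])
  }
  expect_equal(from_grid(g2), from_grid(g))
})

test_that("target assignment follows the reduction policy", {
  N <- 500
  rec <- semg_recording(matrix(0, N, 16), fs = 100)
  w <- segment_windows(rec, windowing_config(200, 50))   # S = 20, t = 5
  ramp <- kinematic_track(matrix(seq_len(N), N, 16), rate = 100)
  ann <- gesture_annotation(data.frame(label = "fist", onset = 0, offset = 5,
                                       repetition = 1L, setting = "static1"))
  g <- to_grid(w)
  te <- assign_targets(g, ramp, ann, policy = "end")
  expect_equal(te$targets[, 1], as.numeric(w$starts + 19))
  tc <- assign_targets(g, ramp, ann, policy = "center")
  expect_equal(tc$targets[, 1], as.numeric(w$starts + 10))
  tm <- assign_targets(g, ramp, ann, policy = "mean")
  expect_equal(tm$targets[, 1], as.numeric(w$starts) + 9.5)

  const <- kinematic_track(matrix(7, N, 16), rate = 100)
  for (pol in c("end", "center", "mean")) {
    expect_true(all(assign_targets(g, const, ann, policy = pol)$targets == 7))
  }
})

test_that("labels cover the annotated event at the target time, else rest", {
  N <- 1000
  rec <- semg_recording(matrix(0, N, 16), fs = 100)
  w <- segment_windows(rec, windowing_config(100, 50))
  kin <- kinematic_track(matrix(0, N, 16), rate = 100)
  ann <- gesture_annotation(data.frame(label = c("fist", "pinch"),
                                       onset = c(2, 6), offset = c(4, 8),
                                       repetition = c(1L, 1L), setting = "static1"))
  g <- assign_targets(to_grid(w), kin, ann)
  t_end <- g$window_times
  expect_true(all(g$labels[t_end >= 2 & t_end < 4] == "fist"))
  expect_true(all(g$labels[t_end >= 6 & t_end < 8] == "pinch"))
  expect_true(all(g$labels[t_end < 2 | (t_end >= 4 & t_end < 6) | t_end >= 8] == "rest"))
  expect_equal(g$repetition[g$labels == "fist"], rep(1L, sum(g$labels == "fist")))
})

test_that("windows overlapping outlier-masked samples are dropped", {
  N <- 400
  rec <- semg_recording(matrix(0, N, 16), fs = 100)
  w <- segment_windows(rec, windowing_config(100, 50))   # S = 10, t = 5
  kin <- kinematic_track(matrix(50, N, 16), rate = 100)
  ann <- gesture_annotation(data.frame(label = "fist", onset = 0, offset = 4,
                                       repetition = 1L, setting = "static1"))
  mask <- list(keep = rep(TRUE, N), rate = 100)
  mask$keep[101:105] <- FALSE
  g <- assign_targets(to_grid(w), kin, ann, outlier_mask = mask)
  full <- assign_targets(to_grid(w), kin, ann)
  dropped <- setdiff(full$starts, g$starts)
  # exactly the windows covering samples 101..105 disappear
  expect_true(all(dropped + 9 >= 101 & dropped <= 105))
  expect_equal(sort(c(dropped, g$starts)), full$starts)
  overlap <- full$starts[full$starts + 9 >= 101 & full$starts <= 105]
  expect_equal(sort(dropped), sort(overlap))
})

test_that("kinematics must be on the window clock", {
  rec <- semg_recording(matrix(0, 200, 16), fs = 100)
  w <- to_grid(segment_windows(rec, windowing_config(100, 50)))
  kin <- kinematic_track(matrix(0, 100, 16), rate = 50)
  ann <- gesture_annotation(data.frame(label = "fist", onset = 0, offset = 1,
                                       repetition = 1L, setting = "static1"))
  expect_error(assign_targets(w, kin, ann), "resample")
})

test_that("augmentation is the identity when disabled and reproducible when seeded", {
  x <- toy_tensor(L = 4, S = 512, fs = 1000)
  id <- augment_windows(x, augment_config(silence_prob = 0, noise_sd = 0))
  expect_equal(id$data, x$data)
  a1 <- augment_windows(x, augment_config(seed = 9))
  a2 <- augment_windows(x, augment_config(seed = 9))
  a3 <- augment_windows(x, augment_config(seed = 10))
  expect_identical(a1$data, a2$data)
  expect_false(identical(a1$data, a3$data))
  expect_equal(dim(a1$data), dim(x$data))
})

test_that("silenced spans are exactly zero and logged faithfully", {
  x <- toy_tensor(L = 6, S = 512, fs = 1000)
  x$data[] <- 1
  a <- augment_windows(x, augment_config(silence_prob = 0.7, noise_sd = 0, seed = 4))
  log <- attr(a, "silence_log")
  expect_gt(nrow(log), 0)
  for (k in seq_len(min(nrow(log), 20))) {
    span <- log$onset[k]:(log$onset[k] + log$duration_samples[k] - 1)
    expect_true(all(a$data[log$window[k], span, log$row[k], log$col[k]] == 0))
  }
  # everything outside logged spans is untouched
  touched <- array(FALSE, dim(x$data))
  for (k in seq_len(nrow(log))) {
    span <- log$onset[k]:(log$onset[k] + log$duration_samples[k] - 1)
    touched[log$window[k], span, log$row[k], log$col[k]] <- TRUE
  }
  expect_true(all(a$data[!touched] == 1))
})

test_that("silence durations span the configured interval with the uniform mean", {
  x <- toy_tensor(L = 700, S = 512, fs = 1000)
  x$data[] <- 0
  a <- augment_windows(x, augment_config(silence_prob = 1, noise_sd = 0, seed = 12))
  d <- attr(a, "silence_log")$duration_ms
  expect_gte(length(d), 1e4)
  expect_true(all(d >= 6 - 1 & d <= 400 + 1))
  expect_equal(mean(d), 203, tolerance = 0.02)
})

test_that("added noise has the configured variance", {
  x <- toy_tensor(L = 16, S = 512, fs = 1000)
  x$data[] <- 0
  a <- augment_windows(x, augment_config(silence_prob = 0, noise_sd = 0.1, seed = 13))
  expect_gt(length(a$data), 1e5)
  expect_equal(var(as.numeric(a$data)), 0.01, tolerance = 0.05)
})

test_that("over-long silence spans are truncated with a warning", {
  x <- toy_tensor(L = 2, S = 16, fs = 1000)   # 16 ms windows
  expect_warning(a <- augment_windows(x, augment_config(silence_prob = 1,
                                                        silence_duration = c(50, 60),
                                                        noise_sd = 0, seed = 2)),
                 "truncat")
  expect_true(all(a$data == 0))
})
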