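# Shared miniature fixtures: low sampling rates and short holds keep the
# simulator fast while exercising every pipeline stage.

tiny_protocol <- function(n_gestures = 3, n_repetitions = 2,
                          hold = 0.6, pause = 0.3, seed = 7L) {
  protocol_config(n_gestures = n_gestures, n_repetitions = n_repetitions,
                  hold_duration = hold, pause_duration = pause,
                  order_seed = seed)
}

tiny_templates <- function(n_gestures = 3, ...) {
  gesture_templates(gestures = default_gestures(n_gestures),
                    transition_time = 0.1, onset_lag = 0.02, ...)
}

tiny_noise <- function(...) {
  noise_model(carrier_band = c(20, 80), line_amps = c(2, 1),
              baseline_sd = 0.5, artifact_rate = 0, ...)
}

tiny_session <- function(seed = 11L, fs = 200, kin_rate = 50, ...) {
  make_session(tiny_protocol(), tiny_templates(), tiny_noise(),
               fs = fs, kin_rate = kin_rate, seed = seed, ...)
}

# steady-state amplitude gain of the sEMG filter chain for a pure tone
tone_gain <- function(freq, fs = 4000, dur = 8, config = preprocess_config(zscore = FALSE)) {
  t <- (seq_len(fs * dur) - 1) / fs
  x <- matrix(sin(2 * pi * freq * t), ncol = 1)[, rep(1, 16)]
  rec <- semg_recording(x, fs = fs)
  out <- filter_semg(rec, config)
  core <- (fs + 1):(fs * (dur - 1))     # trim one second of edges
  sqrt(mean(out$samples[core, 1]^2)) / sqrt(mean(x[core, 1]^2))
}

# a bare window tensor with synthetic content, for decoder unit tests
toy_tensor <- function(L = 8, S = 64, fs = 1000, seed = 1,
                       targets = NULL, labels = NULL) {
  x <- semgdecode:::with_seed(seed, array(stats::rnorm(L * S * 16), c(L, S, 4, 4)))
  if (is.null(targets)) {
    targets <- semgdecode:::with_seed(seed + 1, matrix(stats::rnorm(L * 16, 45, 20), L, 16))
  }
  structure(list(data = x, targets = targets,
                 labels = if (is.null(labels)) rep("g", L) else labels,
                 window_times = seq_len(L), starts = seq_len(L),
                 window_samples = S, stride_samples = 1, fs = fs,
                 layout = default_grid_layout(),
                 channel_ids = sprintf("ch%02d", 1:16)),
            class = "window_tensor")
}
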