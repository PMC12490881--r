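#' End-to-end decoding experiment on a synthetic session
#'
#' Runs the full pipeline on one simulated subject: simulate a session,
#' filter and normalize the sEMG, resample and smooth the kinematics,
#' apply median-deviation outlier rejection, segment plateau windows on
#' the electrode grid, split by repetition, train the transformer decoder
#' with early stopping, and evaluate held-out repetitions with the
#' downstream extra-trees gesture classifier (event-level majority vote).
#'
#' Windows are drawn from the plateau of each hold (after the pose
#' transition and the electromechanical lag have settled) at the
#' configured stride; at most `windows_per_event` evenly spaced windows
#' per event are materialized, which keeps memory and training time at
#' desk scale without touching the acquisition protocol itself.
#'
#' @param seed master seed for the session and training.
#' @param protocol,templates,noise generator settings
#'   ([protocol_config()], [gesture_templates()], [noise_model()]).
#' @param fs,kin_rate sampling rates, Hz.
#' @param setting condition label for the simulated session.
#' @param window_ms,stride_ms windowing parameters (see
#'   [windowing_config()]).
#' @param windows_per_event cap on materialized windows per gesture event.
#' @param split a [split_spec()].
#' @param model a [model_config()]; the default is a compact decoder
#'   (128-sample patches, width 32, one spatial + one temporal block).
#' @param training a [train_config()]; its seed is re-derived from `seed`.
#' @param classifier_trees extra-trees ensemble size.
#' @param shuffled_control also evaluate a label-shuffled classifier
#'   control (chance-level calibration)?
#' @param verbose print progress?
#' @return list with `event_accuracy`, `chance_accuracy`, `plateau_mae`,
#'   `report` (test [classification_report()]), `decoder`, per-window
#'   predictions and the session annotation.
#' @export
decode_experiment <- function(seed = 1L,
                              protocol = protocol_config(),
                              templates = gesture_templates(),
                              noise = noise_model(),
                              fs = 4000, kin_rate = 120,
                              setting = "static1",
                              window_ms = 512, stride_ms = 32,
                              windows_per_event = 25,
                              split = split_spec(),
                              model = model_config(temporal_patch = 256, embed_dim = 32,
                                                   spatial_depth = 1, temporal_depth = 1,
                                                   n_heads = 4, mlp_ratio = 2),
                              training = train_config(learning_rate = 2e-3, batch_size = 64,
                                                      max_epochs = 30, early_stopping_patience = 6,
                                                      lr_decay_epochs = c(20, 26),
                                                      augment = augment_config(silence_prob = 0,
                                                                               noise_sd = 0.1)),
                              classifier_trees = 100,
                              shuffled_control = TRUE,
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating session (seed %d)", seed)
  session <- make_session(protocol, templates, noise, fs = fs, kin_rate = kin_rate,
                          setting = setting, seed = seed)
  annotation <- session$annotation
  say("filtering sEMG (%d samples x 16)", nrow(session$semg$samples))
  filt <- filter_semg(session$semg)
  session$semg <- NULL
  say("kinematics: resample to %g Hz + smooth", fs)
  kin <- resample_kinematics(session$kinematics, fs, n_out = nrow(filt$samples))
  session$kinematics <- NULL
  kin <- smooth_kinematics(kin)
  mask <- reject_outlier_samples(kin, annotation)
  say("outlier rule removed %.3f%% of interval samples", 100 * mask$overall_removed_fraction)
  plan <- segment_windows(filt, windowing_config(window_ms, stride_ms))
  S <- plan$window_samples
  # plateau selection: windows fully inside the settled part of each hold
  settle <- templates$transition_time + templates$onset_lag + 0.1
  start_t <- (plan$starts - 1) / fs
  end_t <- (plan$starts + S - 1 - 1) / fs
  keep_reps <- setdiff(unique(annotation$repetition), split$drop)
  sel <- integer(0)
  for (i in seq_len(nrow(annotation))) {
    if (!(annotation$repetition[i] %in% keep_reps)) next
    cand <- which(start_t >= annotation$onset[i] + settle & end_t <= annotation$offset[i])
    if (!length(cand)) next
    if (length(cand) > windows_per_event) {
      cand <- cand[unique(round(seq(1, length(cand), length.out = windows_per_event)))]
    }
    sel <- c(sel, cand)
  }
  if (!length(sel)) stop_fmt("no plateau windows were selected; holds may be too short for %g ms windows", window_ms)
  say("materializing %d plateau windows of %d samples", length(sel), S)
  tensor <- to_grid(plan, which = sel)
  plan$recording <- NULL; filt <- NULL
  tensor <- assign_targets(tensor, kin, annotation, policy = "end", outlier_mask = mask)
  kin <- NULL
  train_reps <- setdiff(keep_reps, c(split$val, split$test))
  idx_train <- which(tensor$repetition %in% train_reps)
  idx_val <- which(tensor$repetition %in% split$val)
  idx_test <- which(tensor$repetition %in% split$test)
  if (!length(idx_train) || !length(idx_val) || !length(idx_test)) {
    stop_fmt("empty split (train %d / val %d / test %d windows)",
             length(idx_train), length(idx_val), length(idx_test))
  }
  train_t <- subset_windows(tensor, idx_train)
  val_t <- subset_windows(tensor, idx_val)
  test_t <- subset_windows(tensor, idx_test)
  tensor <- NULL
  training$seed <- derive_seed(seed, "training")
  say("training decoder on %d windows (val %d)", length(idx_train), length(idx_val))
  dec <- semg_decoder(train_t, val_t, model = model, training = training)
  say("best epoch %d (val loss %.5f)", dec$best_epoch,
      min(dec$history$val_loss, na.rm = TRUE))
  preds_test <- predict(dec, test_t)
  # plateau angle recovery: compare with the true template pose per window
  tmpl_truth <- templates$angles[test_t$labels, , drop = FALSE]
  plateau_mae <- mean(abs(preds_test - tmpl_truth))
  clf <- fit_classifier(fitted(dec), train_t$labels,
                        n_trees = classifier_trees, seed = derive_seed(seed, "clf"))
  win_pred <- predict(clf, preds_test)
  vote <- majority_vote(win_pred, test_t$event)
  truth_by_event <- annotation$label[as.integer(vote$event)]
  event_accuracy <- mean(vote$label == truth_by_event)
  report <- classification_report(vote$label, truth_by_event,
                                  vocabulary = sort(unique(annotation$label)))
  chance_accuracy <- NA_real_
  if (shuffled_control) {
    shuf <- with_seed(derive_seed(seed, "shuffle-labels"), sample(train_t$labels))
    clf0 <- fit_classifier(fitted(dec), shuf, n_trees = classifier_trees,
                           seed = derive_seed(seed, "clf0"))
    vote0 <- majority_vote(predict(clf0, preds_test), test_t$event)
    chance_accuracy <- mean(vote0$label == truth_by_event)
  }
  list(event_accuracy = event_accuracy,
       chance_accuracy = chance_accuracy,
       plateau_mae = plateau_mae,
       n_test_events = nrow(vote),
       report = report,
       decoder = dec,
       window_predictions = preds_test,
       test_windows = list(labels = test_t$labels, event = test_t$event,
                           targets = test_t$targets),
       outlier_removed_fraction = mask$overall_removed_fraction,
       annotation = annotation)
}
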