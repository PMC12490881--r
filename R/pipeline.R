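#' Pipeline configuration
#'
#' One nested configuration object for a full simulate -> preprocess ->
#' window -> train -> predict -> evaluate run. Every stage seed is
#' derived deterministically from the global `seed`.
#'
#' @param seed global seed.
#' @param run_dir directory for artifacts, manifest and report.
#' @param protocol,templates,noise,windowing,model,training,split nested
#'   stage configurations (each defaulting to its constructor's defaults).
#' @param fs,kin_rate sampling rates, Hz.
#' @param setting condition label.
#' @param stride_ms,window_ms windowing geometry for the run.
#' @param windows_per_event per-event cap on materialized windows.
#' @param persist_session write the simulated session to `run_dir`?
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, run_dir = tempfile("semgdecode_run_"),
                            protocol = protocol_config(),
                            templates = gesture_templates(),
                            noise = noise_model(),
                            windowing = NULL,
                            model = model_config(temporal_patch = 256, embed_dim = 32,
                                                 spatial_depth = 1, temporal_depth = 1,
                                                 n_heads = 4, mlp_ratio = 2),
                            training = train_config(learning_rate = 2e-3, batch_size = 64,
                                                    max_epochs = 30, early_stopping_patience = 6,
                                                    lr_decay_epochs = c(20, 26),
                                                    augment = augment_config(silence_prob = 0,
                                                                             noise_sd = 0.1)),
                            split = split_spec(),
                            fs = 4000, kin_rate = 120, setting = "static1",
                            window_ms = 512, stride_ms = 32,
                            windows_per_event = 25,
                            persist_session = FALSE) {
  cfg <- list(seed = as.integer(seed), run_dir = run_dir,
              protocol = protocol, templates = templates, noise = noise,
              model = model, training = training, split = split,
              fs = fs, kin_rate = kin_rate, setting = setting,
              window_ms = window_ms, stride_ms = stride_ms,
              windows_per_event = windows_per_event,
              persist_session = isTRUE(persist_session))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  required <- c("seed", "run_dir", "protocol", "templates", "noise", "model",
                "training", "split", "fs", "kin_rate", "setting",
                "window_ms", "stride_ms", "windows_per_event")
  missing_f <- setdiff(required, names(cfg))
  if (length(missing_f)) {
    stop_fmt("pipeline config is missing required field(s): %s", paste(missing_f, collapse = ", "))
  }
  stopifnot(inherits(cfg$protocol, "protocol_config"),
            inherits(cfg$templates, "gesture_template_set"),
            inherits(cfg$noise, "noise_model"),
            inherits(cfg$model, "model_config"),
            inherits(cfg$training, "train_config"),
            inherits(cfg$split, "split_spec"))
  invisible(cfg)
}

md5_of <- function(object) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(object, tf, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the full decoding pipeline
#'
#' Executes simulate -> preprocess -> window -> train -> predict ->
#' evaluate with one configuration, writes an evaluation report
#' (`report.json`) and a run manifest (`manifest.json`, with per-stage
#' digests and timings) into `run_dir`, and returns the manifest together
#' with the experiment results. Identical configurations and seeds
#' reproduce identical digests for all deterministic stages.
#'
#' @param config a [pipeline_config()] (or a conforming named list, which
#'   is validated before any stage runs).
#' @param verbose print stage progress?
#' @return list with `manifest` and `results` (see [decode_experiment()]).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  validate_pipeline_config(config)
  dir.create(config$run_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  res <- decode_experiment(seed = config$seed,
                           protocol = config$protocol,
                           templates = config$templates,
                           noise = config$noise,
                           fs = config$fs, kin_rate = config$kin_rate,
                           setting = config$setting,
                           window_ms = config$window_ms, stride_ms = config$stride_ms,
                           windows_per_event = config$windows_per_event,
                           split = config$split,
                           model = config$model, training = config$training,
                           verbose = verbose)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (isTRUE(config$persist_session)) {
    session <- make_session(config$protocol, config$templates, config$noise,
                            fs = config$fs, kin_rate = config$kin_rate,
                            setting = config$setting, seed = config$seed)
    write_session(session, file.path(config$run_dir, "session"), overwrite = TRUE)
  }
  report <- list(
    event_accuracy = res$event_accuracy,
    chance_accuracy = res$chance_accuracy,
    plateau_mae_deg = res$plateau_mae,
    n_test_events = res$n_test_events,
    confusion = res$report$confusion,
    f1 = as.list(res$report$f1),
    outlier_removed_fraction = res$outlier_removed_fraction,
    best_epoch = res$decoder$best_epoch,
    history = res$decoder$history
  )
  jsonlite::write_json(report, file.path(config$run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "semgdecode",
    version = as.character(utils::packageVersion("semgdecode")),
    seed = config$seed,
    config_digest = md5_of(unclass(config)[setdiff(names(config), "run_dir")]),
    stages = list(
      simulate = list(digest = md5_of(res$annotation)),
      train = list(digest = md5_of(res$decoder$params),
                   best_epoch = res$decoder$best_epoch),
      predict = list(digest = md5_of(res$window_predictions)),
      evaluate = list(digest = md5_of(report[c("event_accuracy", "chance_accuracy",
                                               "plateau_mae_deg")]))
    ),
    elapsed_s = elapsed
  )
  jsonlite::write_json(manifest, file.path(config$run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest, results = res)
}

#' Serialize a decoder to a JSON checkpoint
#'
#' Stores the architecture configuration, normalization metadata,
#' training history and all weights as plain JSON, so checkpoints are
#' portable and diffable.
#'
#' @param decoder an `semg_decoder`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "semg_decoder"))
  obj <- list(
    schema = "semgdecode-decoder-v1",
    model = unclass(decoder$model),
    window_samples = decoder$window_samples,
    norm = decoder$norm,
    trained = decoder$trained,
    best_epoch = decoder$best_epoch,
    history = decoder$history,
    params = lapply(decoder$params, function(w) {
      if (is.matrix(w)) list(dim = dim(w), value = as.numeric(w)) else list(value = as.numeric(w))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a decoder from a JSON checkpoint
#'
#' @param path file written by [write_decoder()].
#' @return an `semg_decoder`.
#' @export
read_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "semgdecode-decoder-v1") {
    stop_fmt("'%s' is not a decoder checkpoint", path)
  }
  cfg <- do.call(model_config, obj$model[setdiff(names(obj$model), "output_dim")])
  dec <- build_decoder(cfg, obj$window_samples)
  dec$params <- lapply(obj$params, function(w) {
    if (!is.null(w$dim) && length(w$dim)) matrix(w$value, w$dim[1], w$dim[2]) else as.numeric(w$value)
  })
  dec$norm <- list(mu = as.numeric(obj$norm$mu), sd = as.numeric(obj$norm$sd))
  dec$trained <- isTRUE(obj$trained)
  dec$best_epoch <- obj$best_epoch
  dec$history <- if (!is.null(obj$history)) as.data.frame(obj$history)
  dec
}
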