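#' Write a session bundle to disk
#'
#' The on-disk format is plain text: `semg.tsv` (time x 16 channels,
#' microvolts) and `kinematics.tsv` (time x 16 joints, degrees), both
#' serialized with full round-trip precision, plus a `session.json`
#' sidecar carrying the annotation, electrode grid layout, sampling rates,
#' subject id and metadata. The directory round-trips losslessly through
#' [read_session()].
#'
#' @param bundle a [session_bundle()].
#' @param path directory to create.
#' @param overwrite overwrite an existing session directory? Default FALSE.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path, overwrite = FALSE) {
  stopifnot(inherits(bundle, "session_bundle"))
  if (file.exists(file.path(path, "session.json")) && !overwrite) {
    stop_fmt("session already exists at '%s'; use overwrite = TRUE", path)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_num_tsv <- function(m, file, headers) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(headers, collapse = "\t"), con)
    lines <- do.call(paste, c(lapply(seq_len(ncol(m)), function(j) {
      sprintf("%.17g", m[, j])
    }), sep = "\t"))
    writeLines(lines, con)
  }
  write_num_tsv(bundle$semg$samples, file.path(path, "semg.tsv"), bundle$semg$channel_ids)
  write_num_tsv(bundle$kinematics$angles, file.path(path, "kinematics.tsv"),
                bundle$kinematics$joint_names)
  sidecar <- list(
    schema = "semgdecode-session-v1",
    subject_id = bundle$subject_id,
    fs = bundle$semg$fs,
    kin_rate = bundle$kinematics$rate,
    channel_ids = bundle$semg$channel_ids,
    joint_names = bundle$kinematics$joint_names,
    grid_layout = bundle$semg$grid_layout,
    events = as.data.frame(unclass(bundle$annotation), stringsAsFactors = FALSE),
    metadata = bundle$metadata
  )
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Reads a directory written by [write_session()] (or any conforming
#' layout) and validates all container invariants on load: 16 channels,
#' 16 joints in canonical order, a bijective grid layout and sorted
#' non-overlapping events.
#'
#' @param path session directory.
#' @return a [session_bundle()].
#' @export
read_session <- function(path) {
  sidecar_path <- file.path(path, "session.json")
  if (!file.exists(sidecar_path)) {
    stop_fmt("session sidecar not found: '%s'", sidecar_path)
  }
  sc <- tryCatch(jsonlite::read_json(sidecar_path, simplifyVector = TRUE),
                 error = function(e) stop_fmt("cannot parse sidecar '%s': %s",
                                              sidecar_path, conditionMessage(e)))
  read_num_tsv <- function(file) {
    if (!file.exists(file)) stop_fmt("missing signal file '%s'", file)
    as.matrix(utils::read.table(file, header = TRUE, sep = "\t",
                                colClasses = "numeric", check.names = FALSE))
  }
  semg_m <- read_num_tsv(file.path(path, "semg.tsv"))
  kin_m <- read_num_tsv(file.path(path, "kinematics.tsv"))
  layout <- as.data.frame(sc$grid_layout, stringsAsFactors = FALSE)
  semg <- semg_recording(semg_m, fs = sc$fs, channel_ids = sc$channel_ids,
                         grid_layout = layout)
  kin <- kinematic_track(kin_m, rate = sc$kin_rate, joint_names_ = sc$joint_names)
  events <- as.data.frame(sc$events, stringsAsFactors = FALSE)
  annotation <- gesture_annotation(events)
  meta <- if (is.null(sc$metadata)) list() else as.list(sc$metadata)
  session_bundle(semg, kin, annotation, subject_id = sc$subject_id, metadata = meta)
}

#' Repetition-based split specification
#'
#' The partition used throughout: repetition 1 of every gesture is
#' dropped (subjects adjusting to the task), repetition 5 is the test
#' set, repetition 4 the validation set, and the remaining repetitions
#' train the decoder.
#'
#' @param drop_repetitions repetitions removed entirely (default 1).
#' @param test_repetitions repetitions held out for testing (default 5).
#' @param val_repetitions repetitions held out for validation (default 4).
#' @return a `split_spec`.
#' @export
split_spec <- function(drop_repetitions = 1L, test_repetitions = 5L,
                       val_repetitions = 4L) {
  sets <- list(drop = as.integer(drop_repetitions),
               test = as.integer(test_repetitions),
               val = as.integer(val_repetitions))
  all_named <- unlist(sets)
  if (anyDuplicated(all_named)) {
    stop_fmt("drop/test/val repetition sets must be pairwise disjoint")
  }
  structure(sets, class = "split_spec")
}

#' Partition an annotation by repetition index
#'
#' @param annotation a [gesture_annotation()].
#' @param spec a [split_spec()].
#' @return named list of `train`, `val`, `test` annotations; dropped
#'   repetitions appear in none of them.
#' @export
split_by_repetition <- function(annotation, spec = split_spec()) {
  stopifnot(inherits(annotation, "gesture_annotation"))
  if (!inherits(spec, "split_spec")) stop_fmt("spec must be a split_spec")
  reps <- unique(annotation$repetition)
  named <- c(spec$drop, spec$test, spec$val)
  missing_reps <- setdiff(named, reps)
  if (length(missing_reps)) {
    stop_fmt("repetition(s) %s named in the split do not occur in the annotation",
             paste(missing_reps, collapse = ", "))
  }
  keep_class <- function(df) { class(df) <- c("gesture_annotation", "data.frame"); rownames(df) <- NULL; df }
  train_reps <- setdiff(reps, named)
  list(train = keep_class(annotation[annotation$repetition %in% train_reps, , drop = FALSE]),
       val = keep_class(annotation[annotation$repetition %in% spec$val, , drop = FALSE]),
       test = keep_class(annotation[annotation$repetition %in% spec$test, , drop = FALSE]))
}
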