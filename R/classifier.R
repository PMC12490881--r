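#' Fit the downstream gesture classifier
#'
#' An ensemble of extremely randomized decision trees (random split
#' thresholds, majority vote) mapping the decoder's 16-dimensional joint
#' angle output to gesture labels. Backed by `ranger` with
#' `splitrule = "extratrees"` and no bootstrap resampling, matching the
#' classical extra-trees construction.
#'
#' @param vectors n x 16 matrix of joint-angle vectors (degrees).
#' @param labels gesture label per row.
#' @param n_trees ensemble size (default 100).
#' @param seed RNG seed.
#' @return a `gesture_classifier`.
#' @export
fit_classifier <- function(vectors, labels, n_trees = 100, seed = 1L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(labels)) stop_fmt("labels must match rows of vectors")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) == 1) {
    warning("training labels contain a single class; the classifier will always predict it")
  }
  df <- as.data.frame(vectors)
  names(df) <- sprintf("j%02d", seq_len(ncol(vectors)))
  df$.label <- factor(labels, levels = classes)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, splitrule = "extratrees",
    num.random.splits = 1, replace = FALSE, sample.fraction = 1,
    seed = as.integer(seed), num.threads = 1
  )
  structure(list(fit = fit, classes = classes, n_trees = n_trees,
                 seed = as.integer(seed), n_features = ncol(vectors)),
            class = "gesture_classifier")
}

#' @export
print.gesture_classifier <- function(x, ...) {
  cat(sprintf("<gesture_classifier> extra trees: %d trees, %d classes\n",
              x$n_trees, length(x$classes)))
  invisible(x)
}

#' Predict gesture labels
#'
#' @param object a `gesture_classifier`.
#' @param newdata n x 16 matrix of joint-angle vectors.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.gesture_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_fmt("newdata has %d features; classifier was trained on %d", ncol(newdata), object$n_features)
  }
  df <- as.data.frame(newdata)
  names(df) <- sprintf("j%02d", seq_len(ncol(newdata)))
  as.character(stats::predict(object$fit, data = df, num.threads = 1)$predictions)
}

#' Aggregate window-level votes to event labels
#'
#' Majority vote of a window-level prediction over each gesture event's
#' windows; ties break toward the lexicographically first label.
#'
#' @param window_labels predicted label per window.
#' @param event_id event identifier per window.
#' @return data.frame with one row per event (`event`, `label`, `votes`,
#'   `n_windows`).
#' @export
majority_vote <- function(window_labels, event_id) {
  stopifnot(length(window_labels) == length(event_id))
  ev <- split(as.character(window_labels), event_id)
  out <- data.frame(event = names(ev),
                    label = vapply(ev, function(v) names(which.max(table(v))), character(1)),
                    votes = vapply(ev, function(v) max(table(v)), numeric(1)),
                    n_windows = lengths(ev), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
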