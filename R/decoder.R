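#' Decoder architecture configuration
#'
#' The regressor is a video-vision-transformer of the factorized
#' self-attention family: windows are cut into non-overlapping temporal
#' patches per grid cell, each patch is embedded by a small two-layer
#' (GELU) stem — interference-pattern sEMG carries its information in
#' within-patch power, which a purely linear projection of a zero-mean
#' carrier cannot express — learned spatial and temporal positional
#' embeddings are added, and the token set is
#' passed through `spatial_depth` encoder blocks whose self-attention acts
#' over the 16 grid cells (within each temporal index) followed by
#' `temporal_depth` blocks whose self-attention acts over the temporal
#' tokens (within each grid cell). Mean-pooled tokens are mapped by a
#' final fully connected layer to the 16 joint angles.
#'
#' Defaults are deliberately small so that a decoder trains in minutes on
#' one CPU core; every dimension is configurable.
#'
#' @param temporal_patch samples per temporal token patch (must divide the
#'   window length).
#' @param embed_dim token embedding width (divisible by `n_heads`).
#' @param spatial_depth number of spatial-attention encoder blocks.
#' @param temporal_depth number of temporal-attention encoder blocks.
#' @param n_heads attention heads.
#' @param mlp_ratio hidden-layer expansion factor of the encoder MLPs.
#' @param dropout dropout probability on attention/MLP branches (training
#'   only).
#' @return a `model_config`.
#' @export
model_config <- function(temporal_patch = 32, embed_dim = 64,
                         spatial_depth = 2, temporal_depth = 2,
                         n_heads = 4, mlp_ratio = 4, dropout = 0) {
  if (embed_dim %% n_heads != 0) {
    stop_fmt("embed_dim (%d) must be divisible by n_heads (%d)", embed_dim, n_heads)
  }
  if (temporal_patch < 1) stop_fmt("temporal_patch must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_fmt("dropout must be in [0, 1)")
  structure(list(temporal_patch = as.integer(temporal_patch),
                 embed_dim = as.integer(embed_dim),
                 spatial_depth = as.integer(spatial_depth),
                 temporal_depth = as.integer(temporal_depth),
                 n_heads = as.integer(n_heads),
                 mlp_ratio = mlp_ratio,
                 dropout = dropout,
                 output_dim = 16L),
            class = "model_config")
}

#' Decoder training configuration
#'
#' @param loss regression loss: `"mse"` (default) or `"mae"`, on degrees
#'   (or standardized degrees when `standardize_targets`).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping (needs a validation tensor).
#' @param standardize_targets train on per-joint standardized angles
#'   (predictions are mapped back to degrees).
#' @param augment optional [augment_config()] applied to training batches
#'   only; `NULL` disables augmentation.
#' @param grad_clip global gradient-norm clip (numerical safeguard).
#' @param lr_decay_epochs epochs at which the learning rate is multiplied
#'   by `lr_decay_factor` (step decay; empty for a constant rate).
#' @param lr_decay_factor step-decay multiplier.
#' @param seed seed for initialization, shuffling, dropout, augmentation.
#' @param verbose print per-epoch losses?
#' @return a `train_config`.
#' @export
train_config <- function(loss = c("mse", "mae"), learning_rate = 1e-3,
                         batch_size = 32, max_epochs = 50,
                         early_stopping_patience = 5,
                         standardize_targets = TRUE,
                         augment = NULL, grad_clip = 1,
                         lr_decay_epochs = integer(), lr_decay_factor = 0.3,
                         seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  if (batch_size < 1) stop_fmt("batch_size must be >= 1")
  if (early_stopping_patience < 1) stop_fmt("early_stopping_patience must be >= 1")
  if (!is.null(augment)) stopifnot(inherits(augment, "augment_config"))
  structure(list(loss = loss, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 standardize_targets = standardize_targets,
                 augment = augment, grad_clip = grad_clip,
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 lr_decay_factor = lr_decay_factor,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

check_geometry <- function(cfg, S) {
  if (S %% cfg$temporal_patch != 0) {
    stop_fmt("window length %d is not divisible by temporal_patch %d (would give %.2f temporal tokens x 16 spatial tokens)",
             S, cfg$temporal_patch, S / cfg$temporal_patch)
  }
  S %/% cfg$temporal_patch
}

#' Build an untrained decoder
#'
#' Initializes the transformer weights for a given window length and
#' reports the total parameter count. The returned object supports
#' [predict.semg_decoder()] (with random weights) and can be passed to
#' [semg_decoder()] implicitly through its configuration.
#'
#' @param model a [model_config()].
#' @param window_samples samples per window (S).
#' @param seed initialization seed.
#' @return an `semg_decoder` object with `trained = FALSE`.
#' @export
build_decoder <- function(model = model_config(), window_samples, seed = 1L) {
  nt <- check_geometry(model, window_samples)
  params <- init_params(model, nt, derive_seed(seed, "init"))
  structure(list(params = params, model = model,
                 window_samples = as.integer(window_samples), nt = nt,
                 norm = list(mu = rep(0, 16), sd = rep(1, 16)),
                 history = NULL, trained = FALSE, best_epoch = NA_integer_),
            class = "semg_decoder")
}

#' Number of trainable parameters of a decoder
#'
#' @param decoder an `semg_decoder`.
#' @return integer parameter count.
#' @export
n_parameters <- function(decoder) {
  sum(vapply(decoder$params, length, integer(1)))
}

loss_value <- function(pred, tgt, loss) {
  if (loss == "mse") mean((pred - tgt)^2) else mean(abs(pred - tgt))
}
loss_grad <- function(pred, tgt, loss) {
  if (loss == "mse") 2 * (pred - tgt) / length(pred) else sign(pred - tgt) / length(pred)
}

#' Fit the spatio-temporal transformer decoder
#'
#' Trains the factorized transformer regressor on a window tensor with
#' attached kinematic targets, minimizing the configured loss with Adam.
#' When a validation tensor is supplied, training stops once the
#' validation loss has failed to improve for
#' `early_stopping_patience` epochs and the best-validation weights are
#' restored; otherwise the full epoch budget is used. Augmentation, when
#' configured, is applied to training batches only. All randomness
#' (initialization, shuffling, augmentation, dropout) derives from the
#' training seed, so identical calls are reproducible.
#'
#' @param train_tensor a `window_tensor` with targets ([assign_targets()]).
#' @param val_tensor optional validation `window_tensor` with targets.
#' @param model a [model_config()].
#' @param training a [train_config()].
#' @return an `semg_decoder` fit with `history` (per-epoch train/val
#'   loss), `best_epoch`, normalization metadata and fitted training
#'   predictions (degrees).
#' @export
semg_decoder <- function(train_tensor, val_tensor = NULL,
                         model = model_config(), training = train_config()) {
  stopifnot(inherits(train_tensor, "window_tensor"))
  if (is.null(train_tensor$targets)) stop_fmt("train tensor has no targets; run assign_targets()")
  L <- dim(train_tensor$data)[1]
  if (L == 0) stop_fmt("training split is empty")
  S <- dim(train_tensor$data)[2]
  if (!is.null(val_tensor)) {
    stopifnot(inherits(val_tensor, "window_tensor"))
    if (is.null(val_tensor$targets)) stop_fmt("validation tensor has no targets")
    if (dim(val_tensor$data)[1] == 0) stop_fmt("validation split is empty")
    if (dim(val_tensor$data)[2] != S) stop_fmt("validation window length differs from training")
  }
  dec <- build_decoder(model, S, seed = training$seed)
  cfg <- model
  tgt <- train_tensor$targets
  if (training$standardize_targets) {
    mu <- colMeans(tgt)
    sdv <- apply(tgt, 2, stats::sd)
    sdv[sdv < 1e-8] <- 1
  } else {
    mu <- rep(0, 16); sdv <- rep(1, 16)
  }
  dec$norm <- list(mu = mu, sd = sdv)
  tgt_n <- sweep(sweep(tgt, 2, mu), 2, sdv, "/")
  val_tgt_n <- if (!is.null(val_tensor)) {
    sweep(sweep(val_tensor$targets, 2, mu), 2, sdv, "/")
  }
  p <- dec$params
  state <- adam_init(p)
  nb <- ceiling(L / training$batch_size)
  history <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  best_val <- Inf; best_p <- p; best_epoch <- 0L; stall <- 0L
  eval_loss <- function(p, tensor, tgtn) {
    Lv <- dim(tensor$data)[1]
    tot <- 0
    for (b0 in seq(1, Lv, by = 64)) {
      ii <- b0:min(b0 + 63, Lv)
      fw <- nn_forward(p, cfg, tensor$data[ii, , , , drop = FALSE], train = FALSE)
      tot <- tot + loss_value(fw$pred, tgtn[ii, , drop = FALSE], training$loss) * length(ii)
    }
    tot / Lv
  }
  lr <- training$learning_rate
  for (epoch in seq_len(training$max_epochs)) {
    if (epoch %in% training$lr_decay_epochs) lr <- lr * training$lr_decay_factor
    ord <- with_seed(derive_seed(training$seed, paste0("shuffle", epoch)), sample.int(L))
    ep_loss <- 0
    for (b in seq_len(nb)) {
      ii <- ord[((b - 1) * training$batch_size + 1):min(b * training$batch_size, L)]
      xb <- train_tensor$data[ii, , , , drop = FALSE]
      if (!is.null(training$augment)) {
        acfg <- training$augment
        acfg$seed <- derive_seed(training$seed, sprintf("aug%d_%d", epoch, b))
        xb <- suppressWarnings(augment_windows(xb, acfg, fs = train_tensor$fs))
        attr(xb, "silence_log") <- NULL
      }
      fw <- nn_forward(p, cfg, xb, train = TRUE,
                       drop_seed = derive_seed(training$seed, sprintf("do%d_%d", epoch, b)))
      yb <- tgt_n[ii, , drop = FALSE]
      ep_loss <- ep_loss + loss_value(fw$pred, yb, training$loss) * length(ii)
      grads <- nn_backward(p, cfg, fw$caches, loss_grad(fw$pred, yb, training$loss))
      if (is.finite(training$grad_clip)) grads <- clip_grads(grads, training$grad_clip)
      st <- adam_step(p, grads, state, lr)
      p <- st$p; state <- st$state
    }
    ep_loss <- ep_loss / L
    vl <- if (!is.null(val_tensor)) eval_loss(p, val_tensor, val_tgt_n) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss, val_loss = vl))
    if (training$verbose) {
      message(sprintf("epoch %3d  train %.5f  val %s", epoch, ep_loss,
                      if (is.na(vl)) "-" else sprintf("%.5f", vl)))
    }
    if (!is.null(val_tensor)) {
      if (vl < best_val - 1e-12) {
        best_val <- vl; best_p <- p; best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= training$early_stopping_patience) break
      }
    } else {
      best_p <- p; best_epoch <- epoch
    }
  }
  dec$params <- best_p
  dec$history <- history
  dec$best_epoch <- best_epoch
  dec$trained <- TRUE
  dec$training <- training
  dec$train_labels <- train_tensor$labels
  fitted_n <- predict_core(dec, train_tensor$data)
  dec$fitted <- fitted_n
  dec$train_targets <- train_tensor$targets
  dec
}

predict_core <- function(decoder, data, batch_size = 64) {
  L <- dim(data)[1]
  out <- matrix(0, L, 16)
  for (b0 in seq(1, L, by = batch_size)) {
    ii <- b0:min(b0 + batch_size - 1, L)
    fw <- nn_forward(decoder$params, decoder$model, data[ii, , , , drop = FALSE], train = FALSE)
    out[ii, ] <- fw$pred
  }
  out <- sweep(sweep(out, 2, decoder$norm$sd, "*"), 2, decoder$norm$mu, "+")
  colnames(out) <- joint_names()
  out
}

#' Predict joint angles for a window tensor
#'
#' Inference applies no augmentation or dropout; predictions are returned
#' in degrees, one row per window, aligned to `newdata$window_times`.
#'
#' @param object a fitted (or built) `semg_decoder`.
#' @param newdata a `window_tensor`, or a bare L x S x 4 x 4 array.
#' @param batch_size windows per forward pass.
#' @param ... unused.
#' @return L x 16 matrix of joint angles (degrees).
#' @export
predict.semg_decoder <- function(object, newdata, batch_size = 64, ...) {
  data <- if (inherits(newdata, "window_tensor")) newdata$data else newdata
  d <- dim(data)
  if (length(d) != 4 || d[3] != 4 || d[4] != 4) {
    stop_fmt("newdata must be an L x S x 4 x 4 window tensor (got %s)",
             paste(d, collapse = " x "))
  }
  if (d[2] != object$window_samples) {
    stop_fmt("window length %d does not match the decoder's training geometry (%d samples)",
             d[2], object$window_samples)
  }
  predict_core(object, data, batch_size)
}

#' @export
print.semg_decoder <- function(x, ...) {
  cat(sprintf("<semg_decoder> %s, %d parameters\n",
              if (x$trained) "trained" else "untrained", n_parameters(x)))
  cat(sprintf("  patches: %d x %d samples, embed %d, depths %d spatial + %d temporal, %d heads\n",
              x$nt, x$model$temporal_patch, x$model$embed_dim,
              x$model$spatial_depth, x$model$temporal_depth, x$model$n_heads))
  if (x$trained && nrow(x$history)) {
    last <- x$history[x$best_epoch, ]
    cat(sprintf("  best epoch %d: train loss %.5f, val loss %s\n",
                x$best_epoch, last$train_loss,
                if (is.na(last$val_loss)) "-" else sprintf("%.5f", last$val_loss)))
  }
  invisible(x)
}

#' @export
summary.semg_decoder <- function(object, ...) {
  print(object)
  if (object$trained && !is.null(object$fitted)) {
    res <- object$train_targets - object$fitted
    cat(sprintf("  training MAE %.3f deg (per-joint range %.3f-%.3f)\n",
                mean(abs(res)), min(colMeans(abs(res))), max(colMeans(abs(res)))))
  }
  invisible(object)
}

#' @export
fitted.semg_decoder <- function(object, ...) object$fitted

#' @export
residuals.semg_decoder <- function(object, ...) {
  if (!object$trained) stop_fmt("decoder is not trained")
  object$train_targets - object$fitted
}

#' Plot decoder training history
#'
#' @param x a fitted `semg_decoder`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.semg_decoder <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history)) stop_fmt("no training history to plot")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  if (!is.na(x$best_epoch) && x$best_epoch > 0) graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
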