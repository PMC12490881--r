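test_that("configuration invariants are enforced", {
  expect_error(model_config(embed_dim = 30, n_heads = 4), "divisible")
  expect_error(build_decoder(model_config(temporal_patch = 48), window_samples = 64),
               "not divisible")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(early_stopping_patience = 0), "patience")
})

test_that("an untrained decoder maps one window to 16 finite angles, deterministically", {
  cfg <- model_config(temporal_patch = 16, embed_dim = 16, spatial_depth = 1,
                      temporal_depth = 1, n_heads = 2, mlp_ratio = 2)
  dec <- build_decoder(cfg, window_samples = 64, seed = 3)
  x <- toy_tensor(L = 1, S = 64)
  p1 <- predict(dec, x)
  expect_equal(dim(p1), c(1, 16))
  expect_true(all(is.finite(p1)))
  expect_identical(p1, predict(dec, x))
  expect_equal(colnames(p1), joint_names())
})

test_that("parameter count equals the closed-form architecture bookkeeping", {
  for (case in list(c(P = 16, D = 16, ds = 1, dt = 1, H = 2, r = 2, S = 64),
                    c(P = 32, D = 24, ds = 2, dt = 1, H = 4, r = 4, S = 128))) {
    cfg <- model_config(temporal_patch = case["P"], embed_dim = case["D"],
                        spatial_depth = case["ds"], temporal_depth = case["dt"],
                        n_heads = case["H"], mlp_ratio = case["r"])
    dec <- build_decoder(cfg, window_samples = case["S"], seed = 1)
    P <- case["P"]; D <- case["D"]; nt <- case["S"] / P
    Dh <- case["r"] * D
    stem <- P * D + D + D * D + D            # two-layer patch stem
    pos <- 16 * D + nt * D
    per_block <- 2 * D + 4 * (D * D + D) + 2 * D + D * Dh + Dh + Dh * D + D
    head <- 2 * D + 16 * D * 16 + 16   # per-cell pooled features, concatenated
    expected <- stem + pos + (case["ds"] + case["dt"]) * per_block + head
    expect_equal(n_parameters(dec), unname(expected))
  }
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("semgdecode")
  cfg <- model_config(temporal_patch = 4, embed_dim = 8, spatial_depth = 1,
                      temporal_depth = 1, n_heads = 2, mlp_ratio = 2)
  dec <- build_decoder(cfg, window_samples = 8, seed = 7)
  p <- dec$params
  set.seed(42)
  xb <- array(rnorm(2 * 8 * 16), c(2, 8, 4, 4))
  tgt <- matrix(rnorm(2 * 16), 2, 16)
  loss_of <- function(p) {
    fw <- ns$nn_forward(p, cfg, xb, train = FALSE)
    mean((fw$pred - tgt)^2)
  }
  fw <- ns$nn_forward(p, cfg, xb, train = FALSE)
  grads <- ns$nn_backward(p, cfg, fw$caches, 2 * (fw$pred - tgt) / length(fw$pred))
  eps <- 1e-5
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("d/d %s[%d]", nm, i))
    }
  }
})

test_that("training overfits a small set and is seed-reproducible", {
  tensor <- toy_tensor(L = 12, S = 64, seed = 5)
  cfg <- model_config(temporal_patch = 16, embed_dim = 16, spatial_depth = 1,
                      temporal_depth = 1, n_heads = 2, mlp_ratio = 2)
  tc <- train_config(learning_rate = 3e-3, batch_size = 12, max_epochs = 120, seed = 2)
  dec <- semg_decoder(tensor, NULL, model = cfg, training = tc)
  h <- dec$history
  expect_lt(tail(h$train_loss, 1), 0.05 * h$train_loss[1])
  dec2 <- semg_decoder(tensor, NULL, model = cfg, training = tc)
  expect_identical(dec$history, dec2$history)
  expect_identical(dec$params, dec2$params)
  expect_equal(dim(fitted(dec)), c(12, 16))
  expect_equal(residuals(dec), tensor$targets - fitted(dec))
})

test_that("early stopping halts after patience epochs and restores the best weights", {
  tensor <- toy_tensor(L = 8, S = 32, seed = 6)
  val <- toy_tensor(L = 4, S = 32, seed = 7)
  cfg <- model_config(temporal_patch = 8, embed_dim = 8, spatial_depth = 1,
                      temporal_depth = 0, n_heads = 2, mlp_ratio = 1)
  # zero learning rate: the validation loss can never improve after the
  # first epoch, so patience 1 must stop training at epoch 2
  dec <- semg_decoder(tensor, val, model = cfg,
                      training = train_config(learning_rate = 0, batch_size = 8,
                                              max_epochs = 50,
                                              early_stopping_patience = 1, seed = 1))
  expect_equal(nrow(dec$history), 2)
  expect_equal(dec$best_epoch, 1)
  # restored checkpoint attains the minimum observed validation loss
  dec2 <- semg_decoder(tensor, val, model = cfg,
                       training = train_config(learning_rate = 5e-3, batch_size = 8,
                                               max_epochs = 15,
                                               early_stopping_patience = 3, seed = 1))
  expect_equal(dec2$history$val_loss[dec2$best_epoch], min(dec2$history$val_loss))
})

test_that("batched and batch-of-one inference agree", {
  tensor <- toy_tensor(L = 5, S = 64, seed = 9)
  cfg <- model_config(temporal_patch = 16, embed_dim = 16, spatial_depth = 1,
                      temporal_depth = 1, n_heads = 2, mlp_ratio = 2)
  dec <- build_decoder(cfg, 64, seed = 2)
  all_at_once <- predict(dec, tensor)
  one_by_one <- do.call(rbind, lapply(1:5, function(i) {
    predict(dec, tensor$data[i, , , , drop = FALSE])
  }))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-10)
})

test_that("geometry mismatches at prediction time are rejected", {
  cfg <- model_config(temporal_patch = 16, embed_dim = 16, spatial_depth = 1,
                      temporal_depth = 1, n_heads = 2, mlp_ratio = 2)
  dec <- build_decoder(cfg, 64, seed = 2)
  expect_error(predict(dec, toy_tensor(L = 2, S = 32)), "geometry")
  expect_error(predict(dec, array(0, c(2, 64, 2, 8))), "4 x 4")
})

test_that("decoder checkpoints round-trip through JSON", {
  tensor <- toy_tensor(L = 6, S = 32, seed = 10)
  cfg <- model_config(temporal_patch = 8, embed_dim = 8, spatial_depth = 1,
                      temporal_depth = 1, n_heads = 2, mlp_ratio = 1)
  dec <- semg_decoder(tensor, NULL, model = cfg,
                      training = train_config(max_epochs = 3, batch_size = 6, seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_decoder(dec, f)
  dec2 <- read_decoder(f)
  expect_equal(dec2$params, dec$params)
  expect_equal(predict(dec2, tensor), predict(dec, tensor))
})
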