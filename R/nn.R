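# Internal neural-network primitives for the factorized spatio-temporal
# transformer. Everything is plain matrix algebra with hand-written
# backward passes; gradients are verified against numerical
# differentiation in the test suite.
#
# Token layout convention: a batch of B windows with nt temporal patches
# and 16 grid cells becomes a (B * nt * 16) x D matrix whose rows are
# ordered cell-fastest, then patch, then window:
#   row = s + 16 * (t - 1) + 16 * nt * (b - 1).
# Spatial attention groups are therefore contiguous 16-row blocks; the
# temporal grouping is reached through a precomputed row permutation.

# broadcast-add a length-D vector to every row of an n x D matrix
addb <- function(m, b) m + rep(b, each = nrow(m))

# GELU via the logistic (sigmoid) approximation: x * sigmoid(1.702 x).
# The sigmoid is cached on the forward pass and reused for the gradient.
gelu_sig <- function(x) 1 / (1 + exp(-1.702 * x))

ln_fwd <- function(x, g, b) {
  n <- nrow(x); D <- ncol(x)
  mu <- .rowMeans(x, n, D)
  xc <- x - mu
  v <- .rowMeans(xc * xc, n, D)
  inv <- 1 / sqrt(v + 1e-5)
  xhat <- xc * inv
  list(y = addb(xhat * rep(g, each = n), b), xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  n <- nrow(dy); D <- ncol(dy)
  dxhat <- dy * rep(g, each = n)
  m1 <- .rowMeans(dxhat, n, D)
  m2 <- .rowMeans(dxhat * cache$xhat, n, D)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = .colSums(dy * cache$xhat, n, D), db = .colSums(dy, n, D))
}

# Multi-head self-attention within groups of T tokens. `perm` reorders
# rows so that group members are contiguous and fastest-varying (NULL
# when the natural layout already is, as for spatial groups).
attn_fwd <- function(xn, p, pre, perm, T_, G, H) {
  n <- nrow(xn); D <- ncol(xn)
  dh <- D %/% H
  scl <- 1 / sqrt(dh)
  q <- addb(xn %*% p[[paste0(pre, "wq")]], p[[paste0(pre, "bq")]])
  k <- addb(xn %*% p[[paste0(pre, "wk")]], p[[paste0(pre, "bk")]])
  v <- addb(xn %*% p[[paste0(pre, "wv")]], p[[paste0(pre, "bv")]])
  if (!is.null(perm)) { q <- q[perm, , drop = FALSE]; k <- k[perm, , drop = FALSE]; v <- v[perm, , drop = FALSE] }
  qa <- array(q, c(T_, G, D)); ka <- array(k, c(T_, G, D)); va <- array(v, c(T_, G, D))
  oa <- array(0, c(T_, G, D))
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    hc <- ((h - 1) * dh + 1):(h * dh)
    # scale folded into the queries once
    qh <- lapply(seq_len(T_), function(i) matrix(qa[i, , hc], G, dh) * scl)
    kh <- lapply(seq_len(T_), function(i) matrix(ka[i, , hc], G, dh))
    vh <- lapply(seq_len(T_), function(i) matrix(va[i, , hc], G, dh))
    s <- array(0, c(G, T_, T_))
    for (i in seq_len(T_)) for (j in seq_len(T_)) {
      s[, i, j] <- .rowSums(qh[[i]] * kh[[j]], G, dh)
    }
    sm <- matrix(s, G * T_, T_)
    rmax <- sm[, 1]
    for (j in seq_len(T_)[-1]) rmax <- pmax(rmax, sm[, j])
    ex <- exp(sm - rmax)
    a <- ex / .rowSums(ex, G * T_, T_)
    aa <- array(a, c(G, T_, T_))
    for (i in seq_len(T_)) {
      acc <- matrix(0, G, dh)
      for (j in seq_len(T_)) acc <- acc + aa[, i, j] * vh[[j]]
      oa[i, , hc] <- acc
    }
    heads[[h]] <- list(qh = qh, kh = kh, vh = vh, a = aa)
  }
  om <- matrix(oa, n, D)
  if (!is.null(perm)) { ot <- om; ot[perm, ] <- om } else ot <- om
  y <- addb(ot %*% p[[paste0(pre, "wo")]], p[[paste0(pre, "bo")]])
  list(y = y, cache = list(xn = xn, ot = ot, heads = heads, perm = perm,
                           T_ = T_, G = G, H = H, dh = dh, scl = scl))
}

attn_bwd <- function(dy, cache, p, pre, grads) {
  n <- nrow(dy); D <- ncol(dy)
  T_ <- cache$T_; G <- cache$G; H <- cache$H; dh <- cache$dh; scl <- cache$scl
  grads[[paste0(pre, "wo")]] <- grads[[paste0(pre, "wo")]] + crossprod(cache$ot, dy)
  grads[[paste0(pre, "bo")]] <- grads[[paste0(pre, "bo")]] + colSums(dy)
  dot <- dy %*% t(p[[paste0(pre, "wo")]])
  dom <- if (!is.null(cache$perm)) dot[cache$perm, , drop = FALSE] else dot
  doa <- array(dom, c(T_, G, D))
  dqm <- matrix(0, n, D); dkm <- matrix(0, n, D); dvm <- matrix(0, n, D)
  dqa <- array(0, c(T_, G, D)); dka <- array(0, c(T_, G, D)); dva <- array(0, c(T_, G, D))
  for (h in seq_len(H)) {
    hc <- ((h - 1) * dh + 1):(h * dh)
    hd <- cache$heads[[h]]
    doh <- lapply(seq_len(T_), function(i) matrix(doa[i, , hc], G, dh))
    da <- array(0, c(G, T_, T_))
    dvh <- lapply(seq_len(T_), function(i) matrix(0, G, dh))
    for (i in seq_len(T_)) for (j in seq_len(T_)) {
      da[, i, j] <- .rowSums(doh[[i]] * hd$vh[[j]], G, dh)
      dvh[[j]] <- dvh[[j]] + hd$a[, i, j] * doh[[i]]
    }
    am <- matrix(hd$a, G * T_, T_)
    dam <- matrix(da, G * T_, T_)
    srow <- .rowSums(am * dam, G * T_, T_)
    dsm <- am * (dam - srow)
    ds <- array(dsm, c(G, T_, T_))
    # stored queries carry the 1/sqrt(dh) scale, so dk needs no extra
    # factor while dq picks it up through the keys
    dqh <- lapply(seq_len(T_), function(i) matrix(0, G, dh))
    dkh <- lapply(seq_len(T_), function(i) matrix(0, G, dh))
    for (i in seq_len(T_)) for (j in seq_len(T_)) {
      dsij <- ds[, i, j]
      dqh[[i]] <- dqh[[i]] + (dsij * scl) * hd$kh[[j]]
      dkh[[j]] <- dkh[[j]] + dsij * hd$qh[[i]]
    }
    for (i in seq_len(T_)) {
      dqa[i, , hc] <- dqh[[i]]
      dka[i, , hc] <- dkh[[i]]
      dva[i, , hc] <- dvh[[i]]
    }
  }
  unperm <- function(arr) {
    m <- matrix(arr, n, D)
    if (!is.null(cache$perm)) { out <- m; out[cache$perm, ] <- m; out } else m
  }
  dq <- unperm(dqa); dk <- unperm(dka); dv <- unperm(dva)
  xn <- cache$xn
  grads[[paste0(pre, "wq")]] <- grads[[paste0(pre, "wq")]] + crossprod(xn, dq)
  grads[[paste0(pre, "wk")]] <- grads[[paste0(pre, "wk")]] + crossprod(xn, dk)
  grads[[paste0(pre, "wv")]] <- grads[[paste0(pre, "wv")]] + crossprod(xn, dv)
  grads[[paste0(pre, "bq")]] <- grads[[paste0(pre, "bq")]] + colSums(dq)
  grads[[paste0(pre, "bk")]] <- grads[[paste0(pre, "bk")]] + colSums(dk)
  grads[[paste0(pre, "bv")]] <- grads[[paste0(pre, "bv")]] + colSums(dv)
  dxn <- dq %*% t(p[[paste0(pre, "wq")]]) +
    dk %*% t(p[[paste0(pre, "wk")]]) +
    dv %*% t(p[[paste0(pre, "wv")]])
  list(dx = dxn, grads = grads)
}

mlp_fwd <- function(xn, p, pre) {
  h1 <- addb(xn %*% p[[paste0(pre, "w1")]], p[[paste0(pre, "b1")]])
  s <- gelu_sig(h1)
  hg <- h1 * s
  y <- addb(hg %*% p[[paste0(pre, "w2")]], p[[paste0(pre, "b2")]])
  list(y = y, cache = list(xn = xn, h1 = h1, s = s, hg = hg))
}

mlp_bwd <- function(dy, cache, p, pre, grads) {
  grads[[paste0(pre, "w2")]] <- grads[[paste0(pre, "w2")]] + crossprod(cache$hg, dy)
  grads[[paste0(pre, "b2")]] <- grads[[paste0(pre, "b2")]] + colSums(dy)
  dhg <- dy %*% t(p[[paste0(pre, "w2")]])
  dh1 <- dhg * (cache$s * (1 + 1.702 * cache$h1 * (1 - cache$s)))
  grads[[paste0(pre, "w1")]] <- grads[[paste0(pre, "w1")]] + crossprod(cache$xn, dh1)
  grads[[paste0(pre, "b1")]] <- grads[[paste0(pre, "b1")]] + colSums(dh1)
  list(dx = dh1 %*% t(p[[paste0(pre, "w1")]]), grads = grads)
}

# block prefixes in execution order: spatial encoders then temporal
block_prefixes <- function(cfg) {
  c(if (cfg$spatial_depth > 0) sprintf("s%d_", seq_len(cfg$spatial_depth)),
    if (cfg$temporal_depth > 0) sprintf("t%d_", seq_len(cfg$temporal_depth)))
}

init_params <- function(cfg, nt, seed) {
  D <- cfg$embed_dim; P <- cfg$temporal_patch
  Dh <- round(cfg$mlp_ratio * D)
  rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  with_seed(seed, {
    # two-layer patch stem: interference-pattern sEMG carries its
    # information in the within-patch power, which a purely linear
    # projection of a zero-mean carrier cannot express; the stem's
    # nonlinearity turns patch amplitude into token content before
    # layer normalization
    p <- list(
      pe_w1 = rmat(P, D, sqrt(2 / (P + D))),
      pe_b1 = stats::rnorm(D, 0, 0.1),
      pe_w2 = rmat(D, D, sqrt(2 / (2 * D))),
      pe_b2 = stats::rnorm(D, 0, 0.1),
      pos_s = rmat(16, D, 0.1),
      pos_t = rmat(nt, D, 0.1)
    )
    for (pre in block_prefixes(cfg)) {
      p[[paste0(pre, "ln1_g")]] <- rep(1, D)
      p[[paste0(pre, "ln1_b")]] <- rep(0, D)
      for (w in c("wq", "wk", "wv", "wo")) p[[paste0(pre, w)]] <- rmat(D, D, sqrt(2 / (2 * D)))
      for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- rep(0, D)
      p[[paste0(pre, "ln2_g")]] <- rep(1, D)
      p[[paste0(pre, "ln2_b")]] <- rep(0, D)
      p[[paste0(pre, "w1")]] <- rmat(D, Dh, sqrt(2 / (D + Dh)))
      p[[paste0(pre, "b1")]] <- rep(0, Dh)
      p[[paste0(pre, "w2")]] <- rmat(Dh, D, sqrt(2 / (D + Dh)))
      p[[paste0(pre, "b2")]] <- rep(0, D)
    }
    p$lnf_g <- rep(1, D)
    p$lnf_b <- rep(0, D)
    # head reads the per-cell temporal means concatenated over the grid,
    # so cell-specific amplitude survives pooling structurally
    p$w_out <- rmat(16 * D, cfg$output_dim, 0.5 * sqrt(2 / (16 * D + cfg$output_dim)))
    p$b_out <- rep(0, cfg$output_dim)
    p
  })
}

# batch geometry: index vectors and the temporal-grouping permutation
batch_geometry <- function(B, nt) {
  n <- B * nt * 16L
  bb <- rep(seq_len(B), each = 16L * nt)
  ss <- rep(rep(1:16, each = nt), times = B)
  tt <- rep(seq_len(nt), times = 16L * B)
  perm_t <- ss + 16L * (tt - 1L) + 16L * nt * (bb - 1L)
  list(n = n,
       srow = rep_len(1:16, n),
       trow = rep(rep(seq_len(nt), each = 16L), times = B),
       perm_t = perm_t,
       window_id = rep(seq_len(B), each = 16L * nt),
       # (window, cell) group of each token row; groups sort to
       # cell-fastest within window
       cell_id = rep_len(1:16, n) + 16L * (rep(seq_len(B), each = 16L * nt) - 1L))
}

nn_forward <- function(p, cfg, xb, train = FALSE, drop_seed = 0L) {
  d <- dim(xb)
  B <- d[1]; S <- d[2]
  P <- cfg$temporal_patch; nt <- S %/% P
  geom <- batch_geometry(B, nt)
  n <- geom$n
  # (B,S,4,4) -> tokens (s fastest, then t, then b) x P
  a <- array(xb, c(B, P, nt, 16))
  m <- matrix(aperm(a, c(4, 3, 1, 2)), nrow = n, ncol = P)
  h0 <- addb(m %*% p$pe_w1, p$pe_b1)
  s0 <- gelu_sig(h0)
  e0 <- h0 * s0
  x <- addb(e0 %*% p$pe_w2, p$pe_b2) +
    p$pos_s[geom$srow, , drop = FALSE] + p$pos_t[geom$trow, , drop = FALSE]
  caches <- list(tokens = m, h0 = h0, s0 = s0, e0 = e0, geom = geom, B = B, nt = nt)
  dropmasks <- list()
  use_drop <- train && cfg$dropout > 0
  drop_i <- 0L
  drop_rng <- if (use_drop) derive_seed(drop_seed, "drop") else NULL
  blocks <- block_prefixes(cfg)
  for (pre in blocks) {
    spatial <- substring(pre, 1, 1) == "s"
    T_ <- if (spatial) 16L else nt
    G <- n %/% T_
    perm <- if (spatial) NULL else geom$perm_t
    l1 <- ln_fwd(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    at <- attn_fwd(l1$y, p, pre, perm, T_, G, cfg$n_heads)
    ay <- at$y
    if (use_drop) {
      drop_i <- drop_i + 1L
      mask <- with_seed(drop_rng + drop_i,
                        matrix((stats::runif(n * cfg$embed_dim) >= cfg$dropout) / (1 - cfg$dropout),
                               n, cfg$embed_dim))
      ay <- ay * mask
      dropmasks[[paste0(pre, "attn")]] <- mask
    }
    x <- x + ay
    l2 <- ln_fwd(x, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    mp <- mlp_fwd(l2$y, p, pre)
    my <- mp$y
    if (use_drop) {
      drop_i <- drop_i + 1L
      mask <- with_seed(drop_rng + drop_i,
                        matrix((stats::runif(n * cfg$embed_dim) >= cfg$dropout) / (1 - cfg$dropout),
                               n, cfg$embed_dim))
      my <- my * mask
      dropmasks[[paste0(pre, "mlp")]] <- mask
    }
    x <- x + my
    caches[[paste0(pre, "ln1")]] <- l1
    caches[[paste0(pre, "attn")]] <- at$cache
    caches[[paste0(pre, "ln2")]] <- l2
    caches[[paste0(pre, "mlp")]] <- mp$cache
  }
  # temporal mean per (window, cell), layer-normed, cells concatenated
  pooled <- unname(rowsum(x, geom$cell_id)) / nt  # (B*16) x D, cell-fastest
  lf <- ln_fwd(pooled, p$lnf_g, p$lnf_b)
  hmat <- matrix(aperm(array(lf$y, c(16, B, ncol(x))), c(2, 1, 3)), B)
  pred <- addb(hmat %*% p$w_out, p$b_out)
  caches$lnf <- lf
  caches$hmat <- hmat
  caches$dropmasks <- dropmasks
  list(pred = pred, caches = caches)
}

nn_backward <- function(p, cfg, caches, dpred) {
  geom <- caches$geom
  nt <- caches$nt
  n <- geom$n
  grads <- lapply(p, function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w)))
  B <- caches$B
  D <- ncol(caches$lnf$y)
  grads$w_out <- grads$w_out + crossprod(caches$hmat, dpred)
  grads$b_out <- grads$b_out + colSums(dpred)
  dhmat <- dpred %*% t(p$w_out)                    # B x (16 D)
  dlf <- matrix(aperm(array(dhmat, c(B, 16, D)), c(2, 1, 3)), B * 16L, D)
  lb <- ln_bwd(dlf, caches$lnf, p$lnf_g)
  grads$lnf_g <- grads$lnf_g + lb$dg
  grads$lnf_b <- grads$lnf_b + lb$db
  dx <- lb$dx[geom$cell_id, , drop = FALSE] / nt
  blocks <- rev(block_prefixes(cfg))
  for (pre in blocks) {
    spatial <- substring(pre, 1, 1) == "s"
    mask_m <- caches$dropmasks[[paste0(pre, "mlp")]]
    dmy <- if (is.null(mask_m)) dx else dx * mask_m
    mb <- mlp_bwd(dmy, caches[[paste0(pre, "mlp")]], p, pre, grads)
    grads <- mb$grads
    l2b <- ln_bwd(mb$dx, caches[[paste0(pre, "ln2")]], p[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- grads[[paste0(pre, "ln2_g")]] + l2b$dg
    grads[[paste0(pre, "ln2_b")]] <- grads[[paste0(pre, "ln2_b")]] + l2b$db
    dx <- dx + l2b$dx
    mask_a <- caches$dropmasks[[paste0(pre, "attn")]]
    day <- if (is.null(mask_a)) dx else dx * mask_a
    ab <- attn_bwd(day, caches[[paste0(pre, "attn")]], p, pre, grads)
    grads <- ab$grads
    l1b <- ln_bwd(ab$dx, caches[[paste0(pre, "ln1")]], p[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- grads[[paste0(pre, "ln1_g")]] + l1b$dg
    grads[[paste0(pre, "ln1_b")]] <- grads[[paste0(pre, "ln1_b")]] + l1b$db
    dx <- dx + l1b$dx
  }
  # token embedding
  grads$pos_s <- grads$pos_s + unname(rowsum(dx, geom$srow))
  grads$pos_t <- grads$pos_t + unname(rowsum(dx, geom$trow))
  grads$pe_b2 <- grads$pe_b2 + colSums(dx)
  grads$pe_w2 <- grads$pe_w2 + crossprod(caches$e0, dx)
  de0 <- dx %*% t(p$pe_w2)
  dh0 <- de0 * (caches$s0 * (1 + 1.702 * caches$h0 * (1 - caches$s0)))
  grads$pe_b1 <- grads$pe_b1 + colSums(dh0)
  grads$pe_w1 <- grads$pe_w1 + crossprod(caches$tokens, dh0)
  grads
}

adam_init <- function(p) {
  list(m = lapply(p, function(w) w * 0), v = lapply(p, function(w) w * 0), t = 0L)
}

adam_step <- function(p, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(p)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(p = p, state = state)
}

clip_grads <- function(grads, max_norm) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(tot) && tot > max_norm) grads <- lapply(grads, function(g) g * (max_norm / tot))
  grads
}
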