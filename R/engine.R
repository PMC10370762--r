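# Internal training engine. Tiles are stacked into one block-diagonal sparse
# graph per week so each epoch is a handful of sparse matrix products instead
# of a loop over tiles; gradients are derived analytically (see the methods
# vignette for the full chain).

# Stack a set of prepared tiles: block-diagonal normalized adjacency per week,
# row-bound node features per week, and per-node tile bookkeeping.
stack_tiles <- function(prepared, idx = seq_along(prepared$tiles)) {
  tiles <- prepared$tiles[idx]
  n_weeks <- prepared$n_weeks
  n_nodes <- vapply(tiles, function(t) length(t$node_ids), integer(1))
  node_tile <- rep(seq_along(tiles), n_nodes)
  X <- vector("list", n_weeks)
  Ahat <- vector("list", n_weeks)
  for (t in seq_len(n_weeks)) {
    X[[t]] <- do.call(rbind, lapply(tiles, function(tl) tl$X[[t]]))
    Ahat[[t]] <- Matrix::bdiag(lapply(tiles, function(tl) tl$Anorm[[t]]))
  }
  list(X = X, Ahat = Ahat, node_tile = node_tile, n_per_tile = n_nodes,
       labels = vapply(tiles, function(t) t$label, numeric(1)),
       scores = vapply(tiles, function(t) t$score, numeric(1)),
       tile_ids = vapply(tiles, function(t) t$tile, character(1)),
       n_weeks = n_weeks, n_tiles = length(tiles))
}

# per-dimension standardisation of the stacked node features (fit on the
# training stack, applied everywhere)
feature_moments <- function(stack) {
  all_X <- do.call(rbind, stack$X)
  mu <- colMeans(all_X)
  sd <- apply(all_X, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

standardize_stack <- function(stack, moments) {
  stack$X <- lapply(stack$X, function(X)
    sweep(sweep(X, 2, moments$mu, "-"), 2, moments$sd, "/"))
  stack
}

init_model_params <- function(d, gcn_hidden, lstm_hidden, seed) {
  gcn <- gcn_params(c(d, gcn_hidden, d), seed = seed)
  lstm <- lstm_params(d, lstm_hidden, seed = seed + 1L)
  with_seed(seed + 2L, {
    list(W1 = gcn$W[[1]], b1 = gcn$b[[1]], W2 = gcn$W[[2]], b2 = gcn$b[[2]],
         W_F = lstm$W_F, W_I = lstm$W_I, W_O = lstm$W_O, W_g = lstm$W_g,
         b_F = lstm$b_F, b_I = lstm$b_I, b_O = lstm$b_O, b_C = lstm$b_C,
         u = stats::rnorm(lstm_hidden, 0, 1 / sqrt(lstm_hidden)),
         u_x = stats::rnorm(d, 0, 1 / sqrt(d)), c0 = 0)
  })
}

# Forward pass over a stacked batch. Returns tile probabilities, per-node
# readout state, and (optionally) the caches the backward pass needs.
# readout = "last" uses h_T; "mean" averages the hidden trajectory over weeks.
engine_forward <- function(stack, par, fusion, keep_cache = FALSE,
                           readout = "mean") {
  Tn <- stack$n_weeks
  N <- length(stack$node_tile)
  h <- matrix(0, N, ncol(par$W_F))
  C <- h
  hsum <- h
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    X <- stack$X[[t]]
    AX <- as.matrix(stack$Ahat[[t]] %*% X)
    Z1 <- sweep(AX %*% par$W1, 2, par$b1, "+")
    H1 <- relu(Z1)
    AH1 <- as.matrix(stack$Ahat[[t]] %*% H1)
    Z2 <- sweep(AH1 %*% par$W2, 2, par$b2, "+")
    H2 <- relu(Z2)
    Xp <- fusion$delta * X + (1 - fusion$alpha) * H2
    Z <- cbind(Xp, h)
    Fg <- sigmoid(sweep(Z %*% par$W_F, 2, par$b_F, "+"))
    Ig <- sigmoid(sweep(Z %*% par$W_I, 2, par$b_I, "+"))
    Og <- sigmoid(sweep(Z %*% par$W_O, 2, par$b_O, "+"))
    G <- tanh(sweep(Z %*% par$W_g, 2, par$b_C, "+"))
    C_prev <- C
    C <- Fg * C_prev + Ig * G
    tC <- tanh(C)
    h <- Og * tC
    hsum <- hsum + h
    if (keep_cache) {
      cache[[t]] <- list(AX = AX, m1 = Z1 > 0, AH1 = AH1, m2 = Z2 > 0,
                         Z = Z, Fg = Fg, Ig = Ig, Og = Og, G = G,
                         C_prev = C_prev, tC = tC)
    }
  }
  h_read <- if (readout == "mean") hsum / Tn else h
  pool <- rowsum(h_read, stack$node_tile) / stack$n_per_tile
  # linear skip: the head also sees the tile's node features pooled over
  # nodes and weeks
  Xbar <- Reduce(`+`, stack$X) / Tn
  pool_x <- rowsum(Xbar, stack$node_tile) / stack$n_per_tile
  logit <- as.numeric(pool %*% par$u) + as.numeric(pool_x %*% par$u_x) + par$c0
  list(prob = sigmoid(logit), logit = logit, pool = pool, pool_x = pool_x,
       Xbar = Xbar, h_T = h, h_read = h_read, readout = readout, cache = cache)
}

bce_loss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# Analytic gradients of the mean binary cross-entropy wrt all parameters.
engine_backward <- function(stack, par, fusion, fwd) {
  y <- stack$labels
  Tn <- stack$n_weeks
  d <- ncol(par$W1)            # W1 is d x hidden; input dim = nrow(W1)
  din <- nrow(par$W1)
  hs <- ncol(par$W_F)
  N <- length(stack$node_tile)

  dlogit <- (fwd$prob - y) / stack$n_tiles
  g <- list(u = as.numeric(t(fwd$pool) %*% dlogit),
            u_x = as.numeric(t(fwd$pool_x) %*% dlogit), c0 = sum(dlogit),
            W1 = 0 * par$W1, b1 = 0 * par$b1, W2 = 0 * par$W2, b2 = 0 * par$b2,
            W_F = 0 * par$W_F, W_I = 0 * par$W_I, W_O = 0 * par$W_O,
            W_g = 0 * par$W_g, b_F = 0 * par$b_F, b_I = 0 * par$b_I,
            b_O = 0 * par$b_O, b_C = 0 * par$b_C)
  dpool <- outer(dlogit, par$u)                       # n_tiles x hidden
  dh_read <- dpool[stack$node_tile, , drop = FALSE] / stack$n_per_tile[stack$node_tile]
  mean_readout <- identical(fwd$readout, "mean")
  dh_next <- if (mean_readout) matrix(0, N, hs) else dh_read
  dC_next <- matrix(0, N, hs)

  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dh <- dh_next
    if (mean_readout) dh <- dh + dh_read / Tn
    dC <- dC_next + dh * cc$Og * (1 - cc$tC^2)
    dOg <- dh * cc$tC
    dFg <- dC * cc$C_prev
    dIg <- dC * cc$G
    dG <- dC * cc$Ig
    dC_next <- dC * cc$Fg
    dZF <- dFg * cc$Fg * (1 - cc$Fg)
    dZI <- dIg * cc$Ig * (1 - cc$Ig)
    dZO <- dOg * cc$Og * (1 - cc$Og)
    dZG <- dG * (1 - cc$G^2)
    g$W_F <- g$W_F + t(cc$Z) %*% dZF; g$b_F <- g$b_F + colSums(dZF)
    g$W_I <- g$W_I + t(cc$Z) %*% dZI; g$b_I <- g$b_I + colSums(dZI)
    g$W_O <- g$W_O + t(cc$Z) %*% dZO; g$b_O <- g$b_O + colSums(dZO)
    g$W_g <- g$W_g + t(cc$Z) %*% dZG; g$b_C <- g$b_C + colSums(dZG)
    dZcat <- dZF %*% t(par$W_F) + dZI %*% t(par$W_I) +
      dZO %*% t(par$W_O) + dZG %*% t(par$W_g)
    dXp <- dZcat[, seq_len(din), drop = FALSE]
    dh_next <- dZcat[, din + seq_len(hs), drop = FALSE]

    dH2 <- (1 - fusion$alpha) * dXp
    dZ2 <- dH2 * cc$m2
    g$W2 <- g$W2 + t(cc$AH1) %*% dZ2
    g$b2 <- g$b2 + colSums(dZ2)
    dH1 <- as.matrix(stack$Ahat[[t]] %*% (dZ2 %*% t(par$W2)))
    dZ1 <- dH1 * cc$m1
    g$W1 <- g$W1 + t(cc$AX) %*% dZ1
    g$b1 <- g$b1 + colSums(dZ1)
  }
  g
}

# Convex warm start: logistic regression of the tile labels on the pooled
# node features (the linear skip path), fitted by Adam. The full model then
# trains from this generalising solution instead of a random head.
fit_skip_head <- function(stack, iters = 400, lr = 0.05, wd = 1e-3) {
  Xbar <- Reduce(`+`, stack$X) / stack$n_weeks
  pool_x <- rowsum(Xbar, stack$node_tile) / stack$n_per_tile
  y <- stack$labels
  u_x <- rep(0, ncol(pool_x)); c0 <- 0
  par <- list(u_x = u_x, c0 = c0)
  st <- adam_state(par)
  for (it in seq_len(iters)) {
    p <- sigmoid(as.numeric(pool_x %*% par$u_x) + par$c0)
    dl <- (p - y) / length(y)
    grad <- list(u_x = as.numeric(t(pool_x) %*% dl) + wd * par$u_x,
                 c0 = sum(dl))
    upd <- adam_step(par, grad, st, lr)
    par <- upd$par; st <- upd$state
  }
  par
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) 0 * p), v = lapply(par, function(p) 0 * p),
       t = 0)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(par)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}
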