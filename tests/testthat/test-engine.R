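# The analytic backward pass is checked against central finite differences on
# a small synthetic stack, for both readout modes.

fake_prepared <- function(n_tiles = 3, n_nodes = 4, n_weeks = 3, d = 5,
                          seed = 1) {
  set.seed(seed)
  tiles <- lapply(seq_len(n_tiles), function(i) {
    A <- matrix(rbinom(n_nodes^2, 1, 0.5), n_nodes)
    A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
    list(tile = sprintf("t%02d", i),
         node_ids = sprintf("t%02d_n%d", i, seq_len(n_nodes)),
         X = lapply(seq_len(n_weeks), function(t) matrix(rnorm(n_nodes * d), n_nodes)),
         Anorm = lapply(seq_len(n_weeks), function(t)
           Matrix::Matrix(normalized_adjacency(A), sparse = TRUE)),
         label = rbinom(1, 1, 0.5), score = rnorm(1), n_checkins = 10)
  })
  structure(list(tiles = tiles, dim = as.integer(d),
                 n_weeks = as.integer(n_weeks)),
            class = "glstm_data")
}

test_that("analytic gradients match finite differences", {
  prep <- fake_prepared()
  stack <- gclstm:::stack_tiles(prep)
  fusion <- fusion_params(0.6, 0.3)
  for (readout in c("mean", "last")) {
    par <- gclstm:::init_model_params(5, 4, 3, seed = 2)
    # jitter the zero-initialised biases so no ReLU pre-activation sits on its
    # kink, where finite differences are one-sided
    set.seed(17)
    for (nm in c("b1", "b2", "b_F", "b_I", "b_O", "b_C")) {
      par[[nm]] <- par[[nm]] + rnorm(length(par[[nm]]), 0, 0.05)
    }
    fwd <- gclstm:::engine_forward(stack, par, fusion, keep_cache = TRUE,
                                   readout = readout)
    grad <- gclstm:::engine_backward(stack, par, fusion, fwd)
    loss_at <- function(p) {
      f <- gclstm:::engine_forward(stack, p, fusion, readout = readout)
      gclstm:::bce_loss(f$prob, stack$labels)
    }
    eps <- 1e-6
    set.seed(3)
    for (nm in names(par)) {
      n_probe <- min(4, length(par[[nm]]))
      for (idx in sample(length(par[[nm]]), n_probe)) {
        pp <- par; pp[[nm]][idx] <- pp[[nm]][idx] + eps
        pm <- par; pm[[nm]][idx] <- pm[[nm]][idx] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        ana <- if (is.matrix(grad[[nm]])) grad[[nm]][idx] else grad[[nm]][[idx]]
        expect_lt(abs(ana - num), 1e-6 + 1e-4 * abs(num),
                  label = sprintf("grad %s[%d] (%s readout) err", nm, idx, readout))
      }
    }
  }
})

test_that("stacked forward agrees with composing the public module operations", {
  prep <- fake_prepared(n_tiles = 1, n_nodes = 5, n_weeks = 2, d = 4, seed = 7)
  stack <- gclstm:::stack_tiles(prep)
  par <- gclstm:::init_model_params(4, 3, 2, seed = 5)
  fusion <- fusion_params(0.5, 0.5)
  fwd <- gclstm:::engine_forward(stack, par, fusion, readout = "last")

  gcnp <- structure(list(W = list(par$W1, par$W2), b = list(par$b1, par$b2)),
                    class = "gcn_params")
  lstmp <- structure(list(W_F = par$W_F, W_I = par$W_I, W_O = par$W_O,
                          W_g = par$W_g, b_F = par$b_F, b_I = par$b_I,
                          b_O = par$b_O, b_C = par$b_C, input_dim = 4L,
                          hidden_size = 2L), class = "lstm_params")
  tl <- prep$tiles[[1]]
  series <- lapply(1:2, function(t) {
    H <- gcn_forward(tl$X[[t]], tl$Anorm[[t]], gcnp, normalized = TRUE)
    fuse(tl$X[[t]], H, fusion)
  })
  out <- lstm_forward(series, lstmp)
  pool <- colMeans(out$h_T)
  pool_x <- colMeans((tl$X[[1]] + tl$X[[2]]) / 2) # the head's linear skip input
  expect_equal(as.numeric(fwd$prob),
               gclstm:::sigmoid(sum(pool * par$u) + sum(pool_x * par$u_x) +
                                  par$c0),
               tolerance = 1e-12)
})

test_that("a zero learning rate leaves the initial weights untouched", {
  prep <- fake_prepared()
  fit <- glstm(prep, epochs = 5, learning_rate = 0, weight_decay = 0,
               restarts = 1, train_fraction = 0.7, seed = 1)
  init <- gclstm:::init_model_params(prep$dim, fit$gcn_hidden, fit$lstm_hidden,
                                     seed = fit$seed + 2L)
  expect_equal(fit$par, init, tolerance = 1e-15)
})
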