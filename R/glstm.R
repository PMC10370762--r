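# The user-facing model: prepare tiles, fit, predict.

#' Prepare per-tile model inputs from a world
#'
#' Runs the data pipeline up to the trainable stack: splice check-ins onto
#' POIs, build the per-tile/per-week graphs, aggregate the case edges with
#' fixed seeded attention, and precompute the normalized adjacency operators.
#'
#' @param world A [generate_world()] result, or a list with `pois`,
#'   `checkins`, `cases`, optional `truth`, and either a `config` carrying
#'   `zoom`/`n_weeks` or explicit `zoom`/`n_weeks` arguments.
#' @param splice A [splice_params()] object.
#' @param attention_K Attention heads for case-edge aggregation.
#' @param attention_seed Seed of the fixed attention parameter draw.
#' @param zoom,n_weeks Override the world configuration.
#' @return A list of class `glstm_data`: `tiles` (per tile: `tile`, `node_ids`,
#'   `X` list over weeks, `Anorm` list over weeks, `label`, `score`,
#'   `n_checkins`, `coords`, `categories`, `poi_scores` slot), `dim`,
#'   `n_weeks`, `attention`.
#' @export
prepare_tiles <- function(world, splice = splice_params(), attention_K = 2,
                          attention_seed = 7, zoom = NULL, n_weeks = NULL) {
  zoom <- zoom %||% world$config$zoom
  n_weeks <- n_weeks %||% world$config$n_weeks
  stop_if(is.null(zoom) || is.null(n_weeks), "zoom and n_weeks are required")

  ti <- tile_index(world$checkins$lat, world$checkins$lng, zoom)
  ck_tile <- tile_key(ti$z, ti$x, ti$y)
  tile_ids <- sort(unique(world$pois$tile))
  att <- attention_params(dim = 23, K = attention_K, seed = attention_seed)

  truth <- world$truth
  tiles <- vector("list", length(tile_ids))
  for (k in seq_along(tile_ids)) {
    tid <- tile_ids[k]
    fv <- build_feature_vectors(world$pois[world$pois$tile == tid, ],
                                world$checkins[ck_tile == tid, , drop = FALSE],
                                splice, tile = tid, n_weeks = n_weeks)
    Xs <- vector("list", n_weeks)
    An <- vector("list", n_weeks)
    for (t in seq_len(n_weeks)) {
      gr <- build_tile_graph(fv, world$cases, t)
      gr <- aggregate_case_edges(gr, att)
      Xs[[t]] <- unname(gr$X)
      An[[t]] <- Matrix::Matrix(normalized_adjacency(gr$A), sparse = TRUE)
    }
    lab <- if (!is.null(truth)) truth$label[match(tid, truth$tile)] else NA_real_
    sc <- if (!is.null(truth)) truth$score[match(tid, truth$tile)] else NA_real_
    tiles[[k]] <- list(tile = tid, node_ids = fv$poi_id, X = Xs, Anorm = An,
                       label = as.numeric(lab), score = sc,
                       n_checkins = sum(fv$freq), coords = fv$coords,
                       categories = fv$categories)
  }
  structure(list(tiles = tiles, dim = 23L, n_weeks = as.integer(n_weeks),
                 attention = att, zoom = zoom),
            class = "glstm_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic train/test split of tiles
#'
#' @param tiles Character vector of tile ids (>= 2).
#' @param train_fraction Fraction assigned to training (0 < f < 1).
#' @param seed Integer seed.
#' @return A list with `train` and `test` character vectors (disjoint,
#'   exhaustive).
#' @export
split_tiles <- function(tiles, train_fraction = 0.7, seed = 1) {
  stop_if(length(tiles) < 2, "need at least 2 tiles")
  stop_if(train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must be in (0, 1)")
  n_train <- round(length(tiles) * train_fraction)
  stop_if(n_train == 0 || n_train == length(tiles),
          "train_fraction yields an empty side")
  with_seed(seed, {
    train <- sort(sample(tiles, n_train))
    list(train = train, test = sort(setdiff(tiles, train)))
  })
}

#' Fit the graph-convolutional LSTM tile-risk model
#'
#' End-to-end training of the full stack: for every tile and week, the spliced
#' node features (after case-edge aggregation) pass through a 2-layer spectral
#' GCN, are fused with the raw features, and drive a shared per-node LSTM over
#' the weekly steps; node hiddens at the final week are mean-pooled per tile
#' and an affine head with a sigmoid yields the tile risk score. The loss is
#' binary cross-entropy against the tile labels, minimised by full-batch
#' adaptive-moment gradient descent with analytic gradients. A small
#' validation split of the training tiles drives early stopping.
#'
#' @param world A `synthetic_world` (or anything [prepare_tiles()] accepts),
#'   or an already-prepared `glstm_data` object (then `labels` must be
#'   present in it).
#' @param splice,fusion Parameter objects ([splice_params()],
#'   [fusion_params()]).
#' @param gcn_hidden Hidden width of the GCN (layer widths `d, hidden, d`).
#' @param lstm_hidden LSTM hidden size.
#' @param attention_K Attention heads used during preparation.
#' @param epochs Maximum training epochs.
#' @param learning_rate Initial Adam step size.
#' @param lr_decay Per-epoch multiplicative decay of the step size; values
#'   below 1 anneal the optimiser so the full-batch loss trace settles
#'   monotonically.
#' @param weight_decay L2 penalty on the weight matrices and head (biases are
#'   exempt); the main guard against memorising the training tiles.
#' @param train_fraction Fraction of tiles used for training (70/30 default).
#' @param validation_fraction Fraction of *training* tiles held out for early
#'   stopping (0 disables).
#' @param patience Early-stopping patience in epochs.
#' @param readout `"mean"` pools the per-node hidden trajectory averaged over
#'   all weeks before the head; `"last"` uses only the final week's hidden
#'   state.
#' @param restarts Number of independently initialised fits whose predicted
#'   probabilities are averaged (restart ensembling; tames init-to-init
#'   variance of the non-convex fit).
#' @param loss_floor Stop a restart early once its training loss falls below
#'   this value (the fit has converged on the planted labels).
#' @param seed Integer seed controlling the split and the weight inits.
#' @param verbose Print progress every 50 epochs.
#' @return An object of class `glstm`: trained parameters, loss traces, the
#'   tile split, prepared data and configuration. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `residuals`.
#' @export
glstm <- function(world, splice = splice_params(), fusion = fusion_params(),
                  gcn_hidden = 32, lstm_hidden = 16, attention_K = 2,
                  epochs = 200, learning_rate = 3e-3, lr_decay = 0.997,
                  weight_decay = 1e-2, train_fraction = 0.7,
                  validation_fraction = 0, patience = 50,
                  readout = c("mean", "last"), restarts = 2,
                  loss_floor = 0.005, seed = 1, verbose = FALSE) {
  readout <- match.arg(readout)
  stop_if(restarts < 1, "restarts must be >= 1")
  prepared <- if (inherits(world, "glstm_data")) world else {
    prepare_tiles(world, splice = splice, attention_K = attention_K,
                  attention_seed = seed + 1000L)
  }
  labels <- vapply(prepared$tiles, function(t) t$label, numeric(1))
  stop_if(anyNA(labels), "tile labels are required for fitting")
  tile_ids <- vapply(prepared$tiles, function(t) t$tile, character(1))

  split <- split_tiles(tile_ids, train_fraction, seed)
  train_ids <- split$train
  val_ids <- character(0)
  if (validation_fraction > 0 && length(train_ids) >= 5) {
    n_val <- max(1L, round(length(train_ids) * validation_fraction))
    val_ids <- with_seed(seed + 1L, sort(sample(train_ids, n_val)))
    train_ids <- setdiff(train_ids, val_ids)
  }
  idx_of <- function(ids) match(ids, tile_ids)
  tr <- stack_tiles(prepared, idx_of(train_ids))
  moments <- feature_moments(tr)
  tr <- standardize_stack(tr, moments)
  va <- if (length(val_ids)) {
    standardize_stack(stack_tiles(prepared, idx_of(val_ids)), moments)
  } else NULL

  head_start <- if (epochs > 0 && learning_rate > 0) fit_skip_head(tr) else NULL
  fit_one <- function(init_seed) {
    par <- init_model_params(prepared$dim, gcn_hidden, lstm_hidden,
                             seed = init_seed)
    if (!is.null(head_start)) {
      # start from the convex skip-head solution; damp the random output path
      par$u_x <- head_start$u_x
      par$c0 <- head_start$c0
      par$u <- 0.1 * par$u
    }
    opt <- adam_state(par)
    trace_ep <- numeric(0); trace_tr <- numeric(0); trace_va <- numeric(0)
    best <- list(par = par, val = Inf, epoch = 0L)
    for (ep in seq_len(epochs)) {
      fwd <- engine_forward(tr, par, fusion, keep_cache = TRUE,
                            readout = readout)
      loss <- bce_loss(fwd$prob, tr$labels)
      stop_if(!is.finite(loss), "non-finite training loss; aborting")
      grad <- engine_backward(tr, par, fusion, fwd)
      if (weight_decay > 0) {
        for (nm in c("W1", "W2", "W_F", "W_I", "W_O", "W_g", "u")) {
          grad[[nm]] <- grad[[nm]] + weight_decay * par[[nm]]
        }
      }
      upd <- adam_step(par, grad, opt, learning_rate * lr_decay^(ep - 1))
      par <- upd$par; opt <- upd$state
      vloss <- NA_real_
      if (!is.null(va)) {
        vloss <- bce_loss(engine_forward(va, par, fusion,
                                         readout = readout)$prob, va$labels)
        if (vloss < best$val - 1e-6) {
          best <- list(par = par, val = vloss, epoch = ep)
        }
      }
      trace_ep <- c(trace_ep, ep); trace_tr <- c(trace_tr, loss)
      trace_va <- c(trace_va, vloss)
      if (verbose && ep %% 50 == 0) {
        message(sprintf("epoch %4d  train %.4f  val %s", ep, loss,
                        ifelse(is.na(vloss), "-", sprintf("%.4f", vloss))))
      }
      if (loss < loss_floor) break
      if (!is.null(va) && ep - best$epoch >= patience && best$epoch > 0) break
    }
    if (!is.null(va) && is.finite(best$val) && best$epoch > 0) par <- best$par
    list(par = par, trace = data.frame(epoch = trace_ep, train_loss = trace_tr,
                                       val_loss = trace_va))
  }
  fits <- lapply(seq_len(restarts), function(r) fit_one(seed + 2L + 100L * (r - 1L)))
  par <- fits[[1]]$par
  trace <- fits[[1]]$trace

  structure(list(par = par, pars = lapply(fits, `[[`, "par"),
                 traces = lapply(fits, `[[`, "trace"),
                 moments = moments, readout = readout,
                 fusion = fusion, splice = splice,
                 gcn_hidden = gcn_hidden, lstm_hidden = lstm_hidden,
                 attention = prepared$attention, prepared = prepared,
                 split = list(train = train_ids, validation = val_ids,
                              test = split$test),
                 trace = trace, seed = seed,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs_run = nrow(trace)),
            class = "glstm")
}

# stack a set of tile ids from a prepared object (helper for predict/evaluate)
stack_for <- function(object, tile_ids) {
  all_ids <- vapply(object$prepared$tiles, function(t) t$tile, character(1))
  idx <- match(tile_ids, all_ids)
  stop_if(anyNA(idx), "unknown tile id(s)")
  stack_tiles(object$prepared, idx)
}

#' Predict tile or POI risk scores
#'
#' @param object A fitted [glstm()] model.
#' @param newdata `NULL` (default: the model's held-out test tiles), a
#'   character vector of tile ids, a `glstm_data` object, or a
#'   `synthetic_world` (prepared with the model's splice/attention settings).
#' @param unit `"tile"` for pooled tile scores, `"poi"` for per-node scores
#'   from the same affine head applied to each node's final hidden state.
#' @param threshold Label threshold on the sigmoid score.
#' @param ... Unused.
#' @return A data.frame: `tile`, `score`, `label` (and `poi_id` for
#'   `unit = "poi"`).
#' @export
predict.glstm <- function(object, newdata = NULL, unit = c("tile", "poi"),
                          threshold = 0.5, ...) {
  unit <- match.arg(unit)
  prepared <- object$prepared
  if (is.null(newdata)) {
    stack <- stack_for(object, object$split$test)
  } else if (is.character(newdata)) {
    stack <- stack_for(object, newdata)
  } else {
    if (!inherits(newdata, "glstm_data")) {
      newdata <- prepare_tiles(newdata, splice = object$splice,
                               attention_K = object$attention$K,
                               attention_seed = object$seed + 1000L)
    }
    prepared <- newdata
    stack <- stack_tiles(newdata)
  }
  stack <- standardize_stack(stack, object$moments)
  pars <- object$pars %||% list(object$par)
  fwds <- lapply(pars, function(p)
    engine_forward(stack, p, object$fusion, readout = object$readout %||% "mean"))
  prob <- Reduce(`+`, lapply(fwds, `[[`, "prob")) / length(fwds)
  if (unit == "tile") {
    data.frame(tile = stack$tile_ids, score = as.numeric(prob),
               label = as.integer(prob > threshold),
               stringsAsFactors = FALSE)
  } else {
    node_scores <- Reduce(`+`, Map(function(fwd, p) {
      sigmoid(as.numeric(fwd$h_read %*% p$u) +
                as.numeric(fwd$Xbar %*% p$u_x) + p$c0)
    }, fwds, pars)) / length(fwds)
    all_ids <- vapply(prepared$tiles, function(t) t$tile, character(1))
    poi_ids <- unlist(lapply(stack$tile_ids, function(id)
      prepared$tiles[[match(id, all_ids)]]$node_ids))
    data.frame(tile = rep(stack$tile_ids, stack$n_per_tile),
               poi_id = poi_ids, score = node_scores,
               label = as.integer(node_scores > threshold),
               stringsAsFactors = FALSE)
  }
}

#' @export
print.glstm <- function(x, ...) {
  cat("Graph-convolutional LSTM tile-risk model\n")
  cat(sprintf("  tiles: %d train / %d validation / %d test\n",
              length(x$split$train), length(x$split$validation),
              length(x$split$test)))
  cat(sprintf("  GCN hidden %d, LSTM hidden %d, attention heads %d\n",
              x$gcn_hidden, x$lstm_hidden, x$attention$K))
  cat(sprintf("  epochs run: %d, final training loss %.4f\n",
              x$epochs_run, x$trace$train_loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
summary.glstm <- function(object, ...) {
  pr_train <- predict(object, newdata = object$split$train)
  all_ids <- vapply(object$prepared$tiles, function(t) t$tile, character(1))
  lab <- vapply(object$prepared$tiles, function(t) t$label, numeric(1))
  acc <- function(pr) {
    truth <- lab[match(pr$tile, all_ids)]
    100 * mean(pr$label == truth)
  }
  out <- list(model = object,
              train_accuracy = acc(pr_train),
              test_accuracy = acc(predict(object)),
              final_train_loss = object$trace$train_loss[nrow(object$trace)],
              epochs_run = object$epochs_run)
  class(out) <- "summary.glstm"
  out
}

#' @export
print.summary.glstm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  accuracy: %.1f%% (train) / %.1f%% (held-out tiles)\n",
              x$train_accuracy, x$test_accuracy))
  invisible(x)
}

#' @export
coef.glstm <- function(object, ...) object$par

#' @export
plot.glstm <- function(x, ...) {
  plot(x$trace$epoch, x$trace$train_loss, type = "l", xlab = "epoch",
       ylab = "binary cross-entropy", main = "Training trace", ...)
  if (any(is.finite(x$trace$val_loss))) {
    graphics::lines(x$trace$epoch, x$trace$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' @export
residuals.glstm <- function(object, ...) {
  pr <- predict(object, newdata = object$split$test)
  all_ids <- vapply(object$prepared$tiles, function(t) t$tile, character(1))
  lab <- vapply(object$prepared$tiles, function(t) t$label, numeric(1))
  stats::setNames(pr$score - lab[match(pr$tile, all_ids)], pr$tile)
}
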