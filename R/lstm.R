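# Fusion of raw and convolved features, and the LSTM over weekly steps.
# The cell follows the standard gated form: sigmoid forget/input/output gates
# over the concatenated [input, previous hidden], a tanh candidate, elementwise
# gate products.

#' Fusion parameters
#'
#' The LSTM input at week `t` is `X_p = delta * X + (1 - alpha) * H_gcn`,
#' balancing the raw POI features against the graph-convolved representation.
#'
#' @param delta Weight on the raw features (>= 0, default 0.5).
#' @param alpha Down-weight of the convolved features, in `[0, 1]`
#'   (default 0.5).
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(delta = 0.5, alpha = 0.5) {
  stop_if(delta < 0, "delta must be >= 0")
  stop_if(alpha < 0 || alpha > 1, "alpha must be in [0, 1]")
  structure(list(delta = delta, alpha = alpha), class = "fusion_params")
}

#' Fuse raw and graph-convolved features
#'
#' @param X_t Raw node features at week `t`.
#' @param H_gcn GCN output of the same shape.
#' @param params A [fusion_params()] object.
#' @return `delta * X_t + (1 - alpha) * H_gcn`.
#' @export
fuse <- function(X_t, H_gcn, params = fusion_params()) {
  stop_if(!all(dim(X_t) == dim(H_gcn)), "fuse: shape mismatch")
  params$delta * X_t + (1 - params$alpha) * H_gcn
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM parameters
#'
#' One shared cell applied to every node. Gate weights act on the
#' concatenation `[x, h]` (input dim + hidden dim rows).
#'
#' @param input_dim Input feature dimension.
#' @param hidden_size Hidden/cell dimension.
#' @param seed Integer seed; weights uniform `+-1/sqrt(fan_in)`, biases zero.
#' @return A list of class `lstm_params` with `W_F`, `W_I`, `W_O`, `W_g`
#'   (each `(input_dim + hidden) x hidden`) and biases `b_F`, `b_I`, `b_O`,
#'   `b_C`.
#' @export
lstm_params <- function(input_dim, hidden_size, seed = 1) {
  with_seed(seed, {
    fan <- input_dim + hidden_size
    lim <- 1 / sqrt(fan)
    mk <- function() matrix(stats::runif(fan * hidden_size, -lim, lim),
                            fan, hidden_size)
    structure(list(W_F = mk(), W_I = mk(), W_O = mk(), W_g = mk(),
                   b_F = rep(0, hidden_size), b_I = rep(0, hidden_size),
                   b_O = rep(0, hidden_size), b_C = rep(0, hidden_size),
                   input_dim = as.integer(input_dim),
                   hidden_size = as.integer(hidden_size)),
              class = "lstm_params")
  })
}

#' Zero LSTM state
#'
#' @param n Number of rows (nodes in the batch).
#' @param hidden_size Hidden dimension.
#' @return A list of class `lstm_state` with matrices `h` and `C`.
#' @export
lstm_state <- function(n, hidden_size) {
  structure(list(h = matrix(0, n, hidden_size), C = matrix(0, n, hidden_size)),
            class = "lstm_state")
}

#' One LSTM step
#'
#' Gates `F`, `I`, `O` are sigmoids of affine maps of `[x, h_prev]`; the cell
#' updates as `C = F*C_prev + I*tanh(W_g [x, h_prev] + b_C)` and the hidden
#' output is `h = O * tanh(C)`. Gate values lie strictly in (0, 1) and hidden
#' entries strictly in (-1, 1).
#'
#' @param x Input matrix (n x input_dim); a vector is treated as one row.
#' @param state An `lstm_state` (or `NULL` for the zero state).
#' @param params An [lstm_params()] object.
#' @return The new `lstm_state`, with the gate activations attached as
#'   attribute `"gates"`.
#' @export
lstm_cell <- function(x, state, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stop_if(any(!is.finite(x)), "non-finite LSTM input")
  stop_if(ncol(x) != params$input_dim, "LSTM input dimension mismatch")
  if (is.null(state)) state <- lstm_state(nrow(x), params$hidden_size)
  Z <- cbind(x, state$h)
  Fg <- sigmoid(sweep(Z %*% params$W_F, 2, params$b_F, "+"))
  Ig <- sigmoid(sweep(Z %*% params$W_I, 2, params$b_I, "+"))
  Og <- sigmoid(sweep(Z %*% params$W_O, 2, params$b_O, "+"))
  G <- tanh(sweep(Z %*% params$W_g, 2, params$b_C, "+"))
  C <- Fg * state$C + Ig * G
  h <- Og * tanh(C)
  out <- structure(list(h = h, C = C), class = "lstm_state")
  attr(out, "gates") <- list(F = Fg, I = Ig, O = Og, G = G)
  out
}

#' Run the LSTM over a weekly series
#'
#' Applies [lstm_cell()] sequentially from the zero state.
#'
#' @param series List of input matrices, one per week `t = 1..T`.
#' @param params An [lstm_params()] object.
#' @return A list with `h_T` (final hidden), `h` (list of hidden matrices per
#'   week) and `state` (final `lstm_state`).
#' @export
lstm_forward <- function(series, params) {
  stop_if(length(series) == 0, "empty input series")
  x1 <- series[[1]]
  if (is.null(dim(x1))) x1 <- matrix(x1, nrow = 1)
  state <- lstm_state(nrow(x1), params$hidden_size)
  hs <- vector("list", length(series))
  for (t in seq_along(series)) {
    state <- lstm_cell(series[[t]], state, params)
    hs[[t]] <- state$h
  }
  list(h_T = state$h, h = hs, state = state)
}
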