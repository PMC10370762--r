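# First-order spectral graph convolution over tile graphs.

#' Symmetric normalized adjacency
#'
#' `D^(-1/2) (A + I) D^(-1/2)` with `D = diag(rowSums(A + I))` — the
#' propagation operator of a first-order spectral GCN. Its spectral radius is
#' at most 1.
#'
#' @param A Symmetric nonnegative adjacency matrix (dense or `Matrix` sparse).
#' @return The normalized operator, same storage class family as `A`.
#' @export
#' @examples
#' normalized_adjacency(matrix(c(0, 1, 1, 0), 2)) # all entries 0.5
normalized_adjacency <- function(A) {
  stop_if(nrow(A) != ncol(A), "A must be square")
  if (inherits(A, "Matrix")) {
    stop_if(!Matrix::isSymmetric(A), "A must be symmetric")
    At <- A + Matrix::Diagonal(nrow(A))
    dinv <- 1 / sqrt(Matrix::rowSums(At))
    Matrix::Diagonal(x = dinv) %*% At %*% Matrix::Diagonal(x = dinv)
  } else {
    stop_if(!isSymmetric(unname(A)), "A must be symmetric")
    stop_if(any(A < 0), "A must be nonnegative")
    At <- A + diag(nrow(A))
    dinv <- 1 / sqrt(rowSums(At))
    out <- At * outer(dinv, dinv)
    dimnames(out) <- dimnames(A)
    out
  }
}

relu <- function(x) pmax(x, 0)

#' One graph-convolution layer
#'
#' `H' = ReLU(A_norm %*% H %*% W + b)` with the bias broadcast across nodes.
#'
#' @param H Node feature matrix (n x d_in).
#' @param A_norm Normalized adjacency from [normalized_adjacency()].
#' @param W Weight matrix (d_in x d_out).
#' @param b Bias vector (length d_out).
#' @return The activated feature matrix (n x d_out).
#' @export
gcn_layer <- function(H, A_norm, W, b) {
  stop_if(ncol(H) != nrow(W), "H and W shapes not conformable")
  stop_if(length(b) != ncol(W), "bias length must match W columns")
  Z <- as.matrix(A_norm %*% H %*% W)
  relu(sweep(Z, 2, b, "+"))
}

#' GCN parameters
#'
#' A stack of layer weights for [gcn_forward()]. Weights are initialised
#' uniform on `+-1/sqrt(fan_in)` under the given seed.
#'
#' @param dims Integer vector of layer widths, e.g. `c(13, 32, 13)` for a
#'   2-layer net. At least 2 entries.
#' @param seed Integer seed.
#' @return A list of class `gcn_params` with elements `W` (list) and `b` (list).
#' @export
gcn_params <- function(dims, seed = 1) {
  stop_if(length(dims) < 2, "need at least one layer")
  with_seed(seed, {
    L <- length(dims) - 1
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- 1 / sqrt(dims[l])
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
                       dims[l], dims[l + 1])
      b[[l]] <- rep(0, dims[l + 1])
    }
    structure(list(W = W, b = b, dims = as.integer(dims)), class = "gcn_params")
  })
}

#' Stacked GCN forward pass
#'
#' Applies [gcn_layer()] sequentially with a shared normalized adjacency.
#'
#' @param X Input node features (n x dims[1]).
#' @param A Adjacency matrix (normalized internally unless
#'   `normalized = TRUE`).
#' @param params A [gcn_params()] object.
#' @param normalized Set `TRUE` if `A` is already the normalized operator.
#' @return Output features (n x dims[length(dims)]).
#' @export
gcn_forward <- function(X, A, params, normalized = FALSE) {
  A_norm <- if (normalized) A else normalized_adjacency(A)
  H <- X
  for (l in seq_along(params$W)) {
    H <- gcn_layer(H, A_norm, params$W[[l]], params$b[[l]])
  }
  H
}
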