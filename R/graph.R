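# Per-tile graph: POIs are nodes, case food-access categories contribute the
# edge information. A case's category defines a hyperedge over the tile's POIs
# of that category; the GCN adjacency is its clique expansion. Hyperedge
# features are attention-aggregated and written back onto the nodes.

#' Attention parameters for case-edge aggregation
#'
#' `K`-head additive attention: for head `k`, the unnormalised score of member
#' node `i` on edge `e` is `LeakyReLU(b_k' [W_c c_e ; W p_i])`, softmaxed over
#' the edge's members. Parameters are drawn once (seeded) and act as a fixed
#' featurisation of the case-category structure; see the methods vignette.
#'
#' @param dim Node feature dimension.
#' @param K Number of attention heads (>= 1).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.2).
#' @param seed Integer seed for the parameter draw.
#' @return A list of class `attention_params` with per-head `W_c` (dim x dim),
#'   `W` (dim x dim) and `b` (length `2*dim`).
#' @export
attention_params <- function(dim, K = 2, leaky_slope = 0.2, seed = 1) {
  stop_if(K < 1, "K must be >= 1")
  with_seed(seed, {
    sd0 <- 1 / sqrt(dim)
    heads <- lapply(seq_len(K), function(k) {
      list(W_c = matrix(stats::rnorm(dim * dim, 0, sd0), dim, dim),
           W = matrix(stats::rnorm(dim * dim, 0, sd0), dim, dim),
           b = stats::rnorm(2 * dim, 0, sd0))
    })
    structure(list(K = as.integer(K), dim = as.integer(dim),
                   leaky_slope = leaky_slope, heads = heads),
              class = "attention_params")
  })
}

#' Build the graph of one map tile at one week
#'
#' Nodes are the tile's POIs (ordered by `poi_id`). For every case assigned to
#' the tile and every category with a positive count in the given week, a case
#' edge spans the tile's POIs carrying that category (categories with no
#' matching POI contribute no edge). The binary adjacency `A` connects every
#' pair of POIs sharing at least one case edge (clique expansion), zero
#' diagonal.
#'
#' @param features A `poi_features` object from [build_feature_vectors()].
#' @param cases Long case data.frame (`case_id`, `tile`, `week`, `category`,
#'   `count`); rows for other tiles are ignored.
#' @param week Week index `t`.
#' @return A list of class `tile_graph`: `tile`, `node_ids`, `X` (n x d node
#'   features at week `t`), `A`, `edges` (list of `case_id`, `category`,
#'   `members`), `degree` (of `A + I`), `week`.
#' @export
build_tile_graph <- function(features, cases, week) {
  stopifnot(inherits(features, "poi_features"))
  n <- length(features$poi_id)
  stop_if(n == 0, "empty tile")
  X <- feature_matrix_at(features, week)
  rows <- cases[cases$tile == features$tile & cases$week == week &
                  cases$count > 0, , drop = FALSE]
  bad <- setdiff(unique(rows$category), paste0("A", 1:10))
  stop_if(length(bad) > 0,
          paste("unknown case category:", paste(bad, collapse = ", ")))
  A <- matrix(0, n, n, dimnames = list(features$poi_id, features$poi_id))
  edges <- list()
  if (nrow(rows) > 0) {
    rows <- rows[order(rows$case_id, rows$category), , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      members <- which(features$onehot[, rows$category[r]] > 0)
      if (!length(members)) next
      edges[[length(edges) + 1L]] <- list(case_id = rows$case_id[r],
                                          category = rows$category[r],
                                          members = as.integer(members))
      A[members, members] <- 1
    }
  }
  diag(A) <- 0
  structure(list(tile = features$tile, node_ids = features$poi_id, X = X,
                 A = A, edges = edges, degree = 1 + rowSums(A),
                 week = as.integer(week)),
            class = "tile_graph")
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' Attention coefficients of one case edge
#'
#' The edge representation is initialised as the unweighted mean of its member
#' node features (single-pass resolution of the mutually recursive
#' attention/aggregation definitions); each head then scores every member and
#' softmax-normalises over the edge. Coefficients are strictly positive and
#' sum to 1 per head.
#'
#' @param edge An edge element of a [build_tile_graph()] result.
#' @param graph The `tile_graph`.
#' @param params An [attention_params()] object.
#' @return A `K x |members|` matrix of attention coefficients.
#' @export
edge_attention <- function(edge, graph, params) {
  stop_if(params$dim != ncol(graph$X), "attention dimension mismatch")
  members <- edge$members
  c0 <- colMeans(graph$X[members, , drop = FALSE])
  out <- matrix(NA_real_, params$K, length(members))
  for (k in seq_len(params$K)) {
    h <- params$heads[[k]]
    left <- as.numeric(h$W_c %*% c0)
    scores <- vapply(members, function(i) {
      z <- c(left, as.numeric(h$W %*% graph$X[i, ]))
      leaky_relu(sum(h$b * z), params$leaky_slope)
    }, numeric(1))
    out[k, ] <- softmax(scores)
  }
  out
}

#' Aggregate case edges back onto node features
#'
#' Each edge's representation is the head-averaged, attention-weighted sum of
#' its members' transformed features,
#' `c_e = (1/K) sum_k sum_i alpha_i^k W_c p_i`; every node then receives the
#' mean of its incident edges' representations added to its own features.
#' Nodes with no incident edge are unchanged.
#'
#' @param graph A `tile_graph`.
#' @param params An [attention_params()] object.
#' @return The graph with updated `X` and an `edge_repr` matrix (one row per
#'   edge).
#' @export
aggregate_case_edges <- function(graph, params) {
  stop_if(params$K < 1, "K must be >= 1")
  n <- length(graph$node_ids); d <- ncol(graph$X)
  if (!length(graph$edges)) {
    graph$edge_repr <- matrix(numeric(0), 0, d)
    return(graph)
  }
  add <- matrix(0, n, d)
  incident <- integer(n)
  repr <- matrix(0, length(graph$edges), d)
  for (e in seq_along(graph$edges)) {
    edge <- graph$edges[[e]]
    alpha <- edge_attention(edge, graph, params)
    c_e <- numeric(d)
    for (k in seq_len(params$K)) {
      Wc <- params$heads[[k]]$W_c
      for (j in seq_along(edge$members)) {
        c_e <- c_e + alpha[k, j] * as.numeric(Wc %*% graph$X[edge$members[j], ])
      }
    }
    c_e <- c_e / params$K
    repr[e, ] <- c_e
    add[edge$members, ] <- sweep(add[edge$members, , drop = FALSE], 2, c_e, "+")
    incident[edge$members] <- incident[edge$members] + 1L
  }
  touched <- incident > 0
  graph$X[touched, ] <- graph$X[touched, , drop = FALSE] +
    add[touched, , drop = FALSE] / incident[touched]
  graph$edge_repr <- repr
  graph
}

#' Serialize a tile graph to an edge-list JSON (debugging aid)
#'
#' @param graph A `tile_graph`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tile_graph_json <- function(graph, path) {
  obj <- list(tile = graph$tile, week = graph$week, nodes = graph$node_ids,
              adjacency = which(graph$A > 0, arr.ind = TRUE) |>
                (\(m) data.frame(from = graph$node_ids[m[, 1]],
                                 to = graph$node_ids[m[, 2]]))(),
              edges = lapply(graph$edges, function(e)
                list(case_id = e$case_id, category = e$category,
                     members = graph$node_ids[e$members])))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
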