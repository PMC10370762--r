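# Helpers build a minimal tile with controlled categories.
make_tile_features <- function(cats, tile = "14/4823/6160", n_weeks = 2) {
  tk <- parse_tile_key(tile)
  b <- tile_bounds(tk$z, tk$x, tk$y)
  n <- length(cats)
  lat <- seq(b$lat_min + 1e-4, b$lat_max - 1e-4, length.out = n)
  lng <- seq(b$lng_min + 1e-4, b$lng_max - 1e-4, length.out = n)
  pois <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_poi(sprintf("p%02d", i), lat = lat[i], lng = lng[i], tile = tile,
             categories = cats[i],
             description = paste("burger fries", sprintf("venue0x%d", i)))
  }))
  build_feature_vectors(pois, make_checkin()[0, ], tile = tile,
                        n_weeks = n_weeks)
}

case_row <- function(case_id, tile, week, category, count = 1) {
  data.frame(case_id = case_id, tile = tile, week = week, category = category,
             count = count, stringsAsFactors = FALSE)
}

test_that("case categories induce clique adjacency over matching POIs", {
  fv <- make_tile_features(c("A1", "A1"))
  g <- build_tile_graph(fv, case_row("c1", fv$tile, 1, "A1"), week = 1)
  expect_equal(unname(g$A), matrix(c(0, 1, 1, 0), 2))
  expect_length(g$edges, 1)
  expect_equal(g$edges[[1]]$members, 1:2)
  expect_equal(g$degree, c(p01 = 2, p02 = 2))

  # no cases: empty graph
  g0 <- build_tile_graph(make_tile_features(c("A1", "A2", "A3")),
                         case_row("c", fv$tile, 1, "A1")[0, ], week = 1)
  expect_true(all(g0$A == 0))
  expect_length(g0$edges, 0)

  expect_error(build_tile_graph(fv, case_row("c1", fv$tile, 1, "A77"), 1),
               "unknown case category")
})

test_that("disjoint category edges give disconnected components", {
  fv <- make_tile_features(c("A1", "A1", "A2", "A2"))
  cases <- rbind(case_row("c1", fv$tile, 1, "A1"),
                 case_row("c2", fv$tile, 1, "A2"))
  g <- build_tile_graph(fv, cases, week = 1)
  expect_equal(unname(g$A[1:2, 3:4]), matrix(0, 2, 2))
  expect_equal(unname(g$A[1:2, 1:2]), matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(g$A[3:4, 3:4]), matrix(c(0, 1, 1, 0), 2))
})

test_that("edges only form for weeks with positive case counts", {
  fv <- make_tile_features(c("A1", "A1"))
  cases <- case_row("c1", fv$tile, 2, "A1")
  expect_length(build_tile_graph(fv, cases, week = 1)$edges, 0)
  expect_length(build_tile_graph(fv, cases, week = 2)$edges, 1)
})

test_that("attention coefficients are a softmax over edge members", {
  fv <- make_tile_features(c("A1", "A1", "A1", "A1"))
  g <- build_tile_graph(fv, case_row("c1", fv$tile, 1, "A1"), week = 1)
  params <- attention_params(dim = ncol(g$X), K = 2, seed = 3)
  alpha <- edge_attention(g$edges[[1]], g, params)
  expect_equal(dim(alpha), c(2, 4))
  expect_true(all(alpha > 0))
  expect_equal(rowSums(alpha), c(1, 1), tolerance = 1e-9)

  # independent term-by-term softmax oracle for head 1
  h <- params$heads[[1]]
  c0 <- colMeans(g$X[1:4, ])
  raw <- sapply(1:4, function(i) {
    z <- sum(h$b * c(h$W_c %*% c0, h$W %*% g$X[i, ]))
    if (z > 0) z else params$leaky_slope * z
  })
  expect_equal(alpha[1, ], exp(raw - max(raw)) / sum(exp(raw - max(raw))),
               tolerance = 1e-12)

  # singleton edge: alpha = 1; identical node features: uniform
  g1 <- build_tile_graph(make_tile_features(c("A1", "A2")),
                         case_row("c1", fv$tile, 1, "A1"), week = 1)
  expect_equal(as.numeric(edge_attention(g1$edges[[1]], g1, params)), c(1, 1))
  g$X[2, ] <- g$X[1, ]; g$X[3, ] <- g$X[1, ]; g$X[4, ] <- g$X[1, ]
  expect_equal(as.numeric(edge_attention(g$edges[[1]], g, params)),
               rep(0.25, 8), tolerance = 1e-12)
})

test_that("edge aggregation matches a hand-rolled double loop", {
  fv <- make_tile_features(c("A1", "A1", "A1", "A2"))
  g <- build_tile_graph(fv, rbind(case_row("c1", fv$tile, 1, "A1"),
                                  case_row("c2", fv$tile, 1, "A2")), week = 1)
  params <- attention_params(dim = ncol(g$X), K = 2, seed = 5)
  out <- aggregate_case_edges(g, params)

  # loop oracle for the 3-member A1 edge representation
  alpha <- edge_attention(g$edges[[1]], g, params)
  c_e <- 0
  for (k in 1:2) for (j in 1:3) {
    c_e <- c_e + alpha[k, j] *
      as.numeric(params$heads[[k]]$W_c %*% g$X[g$edges[[1]]$members[j], ])
  }
  c_e <- c_e / 2
  expect_equal(unname(out$edge_repr[1, ]), unname(c_e), tolerance = 1e-12)
  # node 1 has one incident edge: X + c_e
  expect_equal(unname(out$X[1, ]), unname(g$X[1, ] + c_e), tolerance = 1e-12)

  # K = 1, single-member edge, W_c = identity: representation equals the node
  g1 <- build_tile_graph(make_tile_features(c("A1", "A2")),
                         case_row("c1", fv$tile, 1, "A1"), week = 1)
  p1 <- attention_params(dim = ncol(g1$X), K = 1, seed = 1)
  p1$heads[[1]]$W_c <- diag(ncol(g1$X))
  out1 <- aggregate_case_edges(g1, p1)
  expect_equal(unname(out1$edge_repr[1, ]), unname(g1$X[1, ]))

  # K = 2 with identical heads reduces to K = 1
  p2 <- attention_params(dim = ncol(g1$X), K = 2, seed = 1)
  p2$heads[[2]] <- p2$heads[[1]]
  p1b <- p2; p1b$K <- 1L; p1b$heads <- p2$heads[1]
  expect_equal(aggregate_case_edges(g1, p2)$X, aggregate_case_edges(g1, p1b)$X,
               tolerance = 1e-12)
})

test_that("graph construction is deterministic and permutation-equivariant", {
  cfg <- tiny_world_config()
  world <- generate_world(cfg)
  tid <- world$tiles$tile[1]
  pois <- world$pois[world$pois$tile == tid, ]
  ti <- tile_index(world$checkins$lat, world$checkins$lng, cfg$zoom)
  cks <- world$checkins[tile_key(ti$z, ti$x, ti$y) == tid, ]
  fv <- build_feature_vectors(pois, cks, tile = tid, n_weeks = cfg$n_weeks)
  g1 <- build_tile_graph(fv, world$cases, 1)
  g2 <- build_tile_graph(fv, world$cases, 1)
  expect_identical(g1$A, g2$A)

  # permuting the input POI rows leaves the (id-ordered) graph unchanged,
  # i.e. outputs are equivariant to input relabeling
  set.seed(8)
  fvp <- build_feature_vectors(pois[sample(nrow(pois)), ], cks, tile = tid,
                               n_weeks = cfg$n_weeks)
  g3 <- build_tile_graph(fvp, world$cases, 1)
  expect_identical(g1$A, g3$A)
  expect_equal(g1$X, g3$X)
})
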