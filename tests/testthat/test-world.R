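test_that("world configuration validates its invariants", {
  expect_error(world_config(n_tiles = 1), "n_tiles")
  expect_error(world_config(n_weeks = 1), "n_weeks")
  expect_error(world_config(category_weights = numeric(0)), "nonempty")
  expect_error(world_config(category_weights = rep(-1, 10)), "nonnegative")
  expect_error(world_config(bbox = c(40, 39, -74, -73)), "bbox")
  expect_error(world_config(bbox = c(-89, 41, -74, -73)), "Mercator")
  expect_error(world_config(noise_sd = -1), "noise_sd")
})

test_that("identical configurations generate identical worlds", {
  w1 <- generate_world(tiny_world_config(seed = 5))
  w2 <- generate_world(tiny_world_config(seed = 5))
  expect_identical(w1$pois, w2$pois)
  expect_identical(w1$checkins, w2$checkins)
  expect_identical(w1$cases, w2$cases)
  expect_identical(w1$truth, w2$truth)
  w3 <- generate_world(tiny_world_config(seed = 6))
  expect_false(identical(w1$checkins, w3$checkins))
})

test_that("all-zero category weights give zero scores and all-negative labels", {
  cfg <- tiny_world_config(category_weights = rep(0, 10), risk_threshold = 0.5)
  w <- generate_world(cfg)
  expect_true(all(w$truth$score == 0))
  expect_true(all(w$truth$label == 0))
})

test_that("every POI lies inside its tile and every tile has POIs", {
  cfg <- tiny_world_config()
  w <- generate_world(cfg)
  for (i in seq_len(nrow(w$tiles))) {
    b <- tile_bounds(w$tiles$z[i], w$tiles$x[i], w$tiles$y[i])
    sel <- w$pois$tile == w$tiles$tile[i]
    expect_gt(sum(sel), 0)
    expect_true(all(w$pois$lat[sel] >= b$lat_min & w$pois$lat[sel] <= b$lat_max))
    expect_true(all(w$pois$lng[sel] >= b$lng_min & w$pois$lng[sel] <= b$lng_max))
  }
  expect_setequal(w$truth$tile, w$tiles$tile)
})

test_that("planted labels are reproducible by an independent brute-force pass", {
  cfg <- tiny_world_config(seed = 9)
  w <- generate_world(cfg)
  zoom <- cfg$zoom
  ti <- tile_index(w$checkins$lat, w$checkins$lng, zoom)
  ck_tile <- tile_key(ti$z, ti$x, ti$y)
  for (tid in w$truth$tile) {
    pois <- w$pois[w$pois$tile == tid, ]
    pois <- pois[order(pois$poi_id), ]
    cks <- w$checkins[ck_tile == tid, ]
    # brute force: argmax-match each check-in, count per POI/week, dot weights
    counts <- matrix(0, nrow(pois), cfg$n_weeks)
    for (i in seq_len(nrow(cks))) {
      m <- match_checkin(cks[i, ], pois)
      t <- week_index(cks$timestamp[i])
      if (!is.na(m) && t >= 1 && t <= cfg$n_weeks) {
        counts[match(m, pois$poi_id), t] <- counts[match(m, pois$poi_id), t] + 1
      }
    }
    Fc <- numeric(10)
    cats <- strsplit(pois$categories, ",")
    for (p in seq_len(nrow(pois))) {
      for (cc in cats[[p]]) {
        ci <- as.integer(sub("A", "", cc))
        Fc[ci] <- Fc[ci] + mean(counts[p, ])
      }
    }
    score <- sum(cfg$category_weights * Fc)
    expect_equal(score, w$truth$score[w$truth$tile == tid], tolerance = 1e-9)
    expect_equal(as.integer(score > cfg$risk_threshold),
                 w$truth$label[w$truth$tile == tid])
  }
})

test_that("score ranks tiles by their planted category frequency", {
  # weights concentrated on A8: the score must rank exactly with the tiles'
  # realized A8 frequency (Spearman correlation 1 under zero noise)
  wts <- rep(0, 10); wts[8] <- 1
  cfg <- tiny_world_config(seed = 11, category_weights = wts,
                           risk_threshold = 1)
  w <- generate_world(cfg)
  zoom <- cfg$zoom
  ti <- tile_index(w$checkins$lat, w$checkins$lng, zoom)
  ck_tile <- tile_key(ti$z, ti$x, ti$y)
  freq_a8 <- vapply(w$truth$tile, function(tid) {
    pois <- w$pois[w$pois$tile == tid, ]
    cks <- w$checkins[ck_tile == tid, ]
    fv <- build_feature_vectors(pois, cks, tile = tid, n_weeks = cfg$n_weeks)
    sum(t(fv$onehot[, 8]) %*% rowMeans(fv$freq))
  }, numeric(1))
  expect_equal(unname(cor(w$truth$score, freq_a8, method = "spearman")), 1)
})

test_that("check-in generator hits the match fraction exactly", {
  poi <- make_poi()
  for (n in c(1, 7, 10)) {
    for (mf in c(0, 0.3, 0.5, 1)) {
      ck <- generate_checkins_for_poi(poi, n, mf, max_offset_km = 8,
                                      seed = n * 10 + mf, weeks = 1:3)
      expect_equal(nrow(ck), n)
      f <- oracle_weekly_frequency(poi, ck, n_weeks = 3)
      expect_equal(sum(f), round(n * mf))
    }
  }
  expect_equal(nrow(generate_checkins_for_poi(poi, 0, 1, seed = 1)), 0)
  expect_error(generate_checkins_for_poi(poi, 5, 1, max_offset_km = -1),
               "max_offset_km")
  expect_error(generate_checkins_for_poi(poi, -1, 1), "n must be")
})

test_that("noise can flip labels relative to the noiseless world", {
  base <- generate_world(tiny_world_config(seed = 3))
  noisy <- generate_world(tiny_world_config(seed = 3, noise_sd = 15))
  # same records, perturbed scores
  expect_identical(base$checkins, noisy$checkins)
  expect_false(all(base$truth$score == noisy$truth$score))
})
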