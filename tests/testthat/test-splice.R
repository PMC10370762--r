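test_that("similarity is 10x cosine with the documented edge cases", {
  expect_equal(similarity(c(a = 1, b = 1), c(a = 1, b = 1)), 10)
  expect_equal(similarity(c(a = 1), c(b = 1)), 0)
  expect_equal(similarity(c(a = 1, b = 1), c(a = 1)), 10 / sqrt(2))
  expect_equal(similarity(integer(0), c(a = 1)), 0)
  expect_equal(similarity(c(a = 0, b = 0), c(a = 1)), 0)
  expect_error(similarity(c(a = -1), c(a = 1)), "nonnegative")
})

test_that("similarity is symmetric and scale-invariant", {
  set.seed(7)
  vocab <- letters[1:12]
  for (i in 1:50) {
    p <- setNames(rpois(12, 1), vocab)
    n <- setNames(rpois(12, 1), vocab)
    expect_equal(similarity(p, n), similarity(n, p))
    expect_equal(similarity(3.7 * p, n), similarity(p, n), tolerance = 1e-12)
    # dot-product oracle
    denom <- sqrt(sum(p^2)) * sqrt(sum(n^2))
    expected <- if (denom == 0) 0 else 10 * sum(p * n) / denom
    expect_equal(similarity(p, n), expected, tolerance = 1e-12)
  }
})

test_that("haversine matches the closed-form equatorial arc and is metric-like", {
  expect_equal(haversine_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(haversine_km(12.3, 45.6, 12.3, 45.6), 0)
  set.seed(13)
  lat <- runif(300, -80, 80); lng <- runif(300, -180, 180)
  i <- sample(300, 100, TRUE); j <- sample(300, 100, TRUE); k <- sample(300, 100, TRUE)
  d_ij <- haversine_km(lat[i], lng[i], lat[j], lng[j])
  d_ji <- haversine_km(lat[j], lng[j], lat[i], lng[i])
  expect_equal(d_ij, d_ji)
  d_ik <- haversine_km(lat[i], lng[i], lat[k], lng[k])
  d_kj <- haversine_km(lat[k], lng[k], lat[j], lng[j])
  expect_true(all(d_ij <= d_ik + d_kj + 1e-9))
})

test_that("haversine agrees with the geosphere reference implementation", {
  set.seed(21)
  a <- cbind(runif(50, -180, 180), runif(50, -80, 80)) # lng, lat
  b <- cbind(runif(50, -180, 180), runif(50, -80, 80))
  ref <- geosphere::distHaversine(a, b, r = 6371000) / 1000
  expect_equal(haversine_km(a[, 2], a[, 1], b[, 2], b[, 1]), ref,
               tolerance = 1e-9)
})

test_that("match_checkin applies strict gates and documented tie-breaks", {
  ck <- make_checkin(text = "burger fries pizza")
  cand <- make_poi("p1", description = "burger fries pizza")
  expect_equal(match_checkin(ck, cand), "p1")
  expect_equal(match_checkin(ck, cand[0, ]), NA_character_)

  # similarity exactly at the threshold is rejected (strict >)
  p <- c(rep("burger", 1), rep("zz", 100)) # cos = 1/sqrt(101) ~ 0.0995
  weak <- make_poi("p2", description = paste(p, collapse = " "))
  params <- splice_params(sim_threshold = similarity(
    tokenize(weak$description), tokenize("burger")))
  expect_equal(match_checkin(make_checkin(text = "burger"), weak, params),
               NA_character_)

  # two qualifying candidates: higher similarity wins
  two <- rbind(make_poi("pa", description = "burger fries pizza shake soda"),
               make_poi("pb", description = "burger fries pizza"))
  expect_equal(match_checkin(ck, two), "pb") # exact token match, cos = 1
  # tie on similarity: nearest wins, then lexicographic id
  tie <- rbind(make_poi("pc", lat = 40.701, description = "burger"),
               make_poi("pa", lat = 40.700, description = "burger"))
  expect_equal(match_checkin(make_checkin(text = "burger", lat = 40.7), tie), "pa")
})

test_that("weekly_visit_frequency equals the brute-force filter-and-count", {
  poi <- make_poi()
  set.seed(31)
  for (mf in c(0, 0.5, 1)) {
    ck <- generate_checkins_for_poi(poi, 20, mf, max_offset_km = 8,
                                    seed = 100 + mf * 10, weeks = 1:4)
    f <- weekly_visit_frequency(poi, ck, n_weeks = 4)
    expect_equal(f, oracle_weekly_frequency(poi, ck, n_weeks = 4))
    expect_equal(sum(f), round(20 * mf))
  }
})

test_that("the distance gate is strictly below 3 km", {
  poi <- make_poi()
  # place a check-in at exactly 3.0 km due east along the great circle
  at3 <- gclstm:::destination_point(poi$lat, poi$lng, pi / 2, 3.0)
  ck <- make_checkin(lat = at3$lat, lng = at3$lng, text = poi$description)
  expect_equal(haversine_km(poi$lat, poi$lng, ck$lat, ck$lng), 3, tolerance = 1e-9)
  expect_equal(sum(weekly_visit_frequency(poi, ck, n_weeks = 1)), 0)
  just_in <- gclstm:::destination_point(poi$lat, poi$lng, pi / 2, 2.99)
  ck2 <- make_checkin(lat = just_in$lat, lng = just_in$lng, text = poi$description)
  expect_equal(sum(weekly_visit_frequency(poi, ck2, n_weeks = 1)), 1)
})

test_that("build_feature_vectors scales coordinates within the tile bbox", {
  tk <- tile_index(40.7, -74.0, 14)
  tid <- tile_key(tk$z, tk$x, tk$y)
  b <- tile_bounds(tk$z, tk$x, tk$y)
  pois <- rbind(
    make_poi("p1", lat = b$lat_min, lng = b$lng_min, tile = tid),
    make_poi("p2", lat = (b$lat_min + b$lat_max) / 2,
             lng = (b$lng_min + b$lng_max) / 2, tile = tid))
  fv <- build_feature_vectors(pois, make_checkin()[0, ], tile = tid, n_weeks = 2)
  expect_equal(unname(fv$scaled[1, ]), c(0, 0))
  expect_equal(unname(fv$scaled[2, ]), c(5, 5), tolerance = 1e-9)
  expect_warning(
    build_feature_vectors(make_poi(), make_checkin()[0, ], n_weeks = 2),
    "degenerate")
})

test_that("the feature frequency matrix equals an independent recount", {
  cfg <- tiny_world_config()
  world <- generate_world(cfg)
  tid <- world$tiles$tile[2]
  pois <- world$pois[world$pois$tile == tid, ]
  ti <- tile_index(world$checkins$lat, world$checkins$lng, cfg$zoom)
  cks <- world$checkins[tile_key(ti$z, ti$x, ti$y) == tid, ]
  fv <- build_feature_vectors(pois, cks, tile = tid, n_weeks = cfg$n_weeks)

  # oracle: re-match every check-in by the documented argmax rule and count
  recount <- matrix(0L, nrow(pois), cfg$n_weeks,
                    dimnames = list(sort(pois$poi_id), NULL))
  for (i in seq_len(nrow(cks))) {
    m <- match_checkin(cks[i, ], pois)
    t <- week_index(cks$timestamp[i])
    if (!is.na(m) && t >= 1 && t <= cfg$n_weeks) {
      recount[m, t] <- recount[m, t] + 1L
    }
  }
  expect_equal(unname(fv$freq), unname(recount))
})

test_that("adding one qualifying check-in increments exactly one week", {
  poi <- make_poi()
  ck <- generate_checkins_for_poi(poi, 12, 0.5, max_offset_km = 8, seed = 9,
                                  weeks = 1:4)
  f0 <- weekly_visit_frequency(poi, ck, n_weeks = 4)
  extra <- make_checkin("cx", lat = poi$lat, lng = poi$lng,
                        text = poi$description, week = 3)
  f1 <- weekly_visit_frequency(poi, rbind(ck, extra), n_weeks = 4)
  expect_equal(f1 - f0, c(0L, 0L, 1L, 0L))
})
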