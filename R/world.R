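# Synthetic-world generator: tiles, POIs, check-in streams and case profiles
# with a planted tile-level risk signal, so every downstream stage of the
# pipeline has ground truth. The generator is first-class, tested code.

#' Configuration of a synthetic world
#'
#' Defines the study conditions the generator emulates: a bounding box tiled at
#' a slippy zoom level, POIs clustered per tile with food-access categories, a
#' weekly check-in stream over `n_weeks` Monday-starting weeks (week 1 =
#' 2020-01-06), and case profiles whose category mix encodes the planted risk
#' signal. The true tile score is
#' `dot(category_weights, mean weekly per-category matched check-in frequency)`
#' plus Gaussian noise; the label is `score > risk_threshold`.
#'
#' @param n_tiles Number of map tiles (>= 2).
#' @param pois_per_tile POIs per tile.
#' @param n_users Distinct check-in user ids.
#' @param n_cases Number of case profiles (assigned to tiles uniformly).
#' @param n_weeks Weekly bins `T` (>= 2).
#' @param category_weights Nonnegative 10-vector of planted risk weights per
#'   category A1-A10. The default up-weights fast food, convenience stores and
#'   supercenters, the venue types that dominate high-calorie food acquisition.
#' @param risk_threshold Score threshold for the binary tile label. `NULL`
#'   (default) estimates the median of the score distribution under this
#'   configuration by a small deterministic Monte Carlo, so labels are roughly
#'   class-balanced.
#' @param noise_sd Standard deviation of Gaussian noise added to the true score.
#' @param bbox `c(lat_min, lat_max, lng_min, lng_max)` in degrees; latitudes
#'   must lie within the Web Mercator range.
#' @param zoom Slippy zoom level of the tiling (default 14, ~2.4 km tiles).
#' @param seed Integer RNG seed; the whole world is a deterministic function of
#'   the configuration.
#' @param match_fraction Fraction of generated check-ins that pass both
#'   splicing gates against their target POI.
#' @param visit_rate Expected matched check-ins per POI per week, before the
#'   tile's planted category intensity multiplier.
#' @param case_visits_per_week Expected total weekly category visits per case.
#' @param margin_frac Planted separation: each tile's intensity profile is
#'   rejection-sampled until its expected score is at least
#'   `margin_frac * risk_threshold` away from the threshold, so the planted
#'   labels are recoverable rather than coin flips on sampling noise. Set 0 to
#'   disable.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_tiles = 60, pois_per_tile = 20, n_users = 500,
                         n_cases = 180, n_weeks = 12,
                         category_weights = c(0.5, 0.2, 0.8, 0.3, 0.8,
                                              0.2, 0.3, 1.0, 0.1, 0.1),
                         risk_threshold = NULL, noise_sd = 0,
                         bbox = c(40.4, 41.3, -74.6, -73.4), zoom = 14,
                         seed = 1, match_fraction = 0.7, visit_rate = 1.0,
                         case_visits_per_week = 10, margin_frac = 0.15) {
  stop_if(length(category_weights) == 0, "category_weights must be nonempty")
  stop_if(length(category_weights) != 10 || any(category_weights < 0),
          "category_weights must be 10 nonnegative reals")
  stop_if(n_tiles < 2, "n_tiles must be >= 2")
  stop_if(n_weeks < 2, "n_weeks must be >= 2")
  stop_if(any(c(pois_per_tile, n_users, n_cases) < 1), "counts must be positive")
  stop_if(length(bbox) != 4 || bbox[1] >= bbox[2] || bbox[3] >= bbox[4],
          "bbox must be c(lat_min, lat_max, lng_min, lng_max) with min < max")
  stop_if(bbox[1] < -MAX_MERCATOR_LAT || bbox[2] > MAX_MERCATOR_LAT,
          "bbox latitudes outside Web Mercator range")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  stop_if(match_fraction < 0 || match_fraction > 1,
          "match_fraction must be in [0, 1]")
  cfg <- structure(list(n_tiles = as.integer(n_tiles),
                        pois_per_tile = as.integer(pois_per_tile),
                        n_users = as.integer(n_users),
                        n_cases = as.integer(n_cases),
                        n_weeks = as.integer(n_weeks),
                        category_weights = as.numeric(category_weights),
                        risk_threshold = risk_threshold,
                        noise_sd = noise_sd, bbox = bbox,
                        zoom = as.integer(zoom), seed = as.integer(seed),
                        match_fraction = match_fraction,
                        visit_rate = visit_rate,
                        case_visits_per_week = case_visits_per_week,
                        margin_frac = margin_frac),
                   class = "world_config")
  if (is.null(cfg$risk_threshold)) cfg$risk_threshold <- default_risk_threshold(cfg)
  cfg
}

# sdlog of the per-tile, per-category lognormal intensity multiplier; a design
# constant of the generator (spread of the planted signal across tiles)
.INTENSITY_SDLOG <- 0.8
.P_TWO_CATEGORIES <- 0.3

#' Default risk threshold for a configuration
#'
#' Approximates the median of the planted tile-score distribution under the
#' given configuration by simulating the generator's structural score model
#' (lognormal tile intensities, Poisson weekly counts) with a fixed internal
#' seed. Using the median keeps the binary tile labels close to class balance.
#'
#' @param config A [world_config()] (its `risk_threshold` field is ignored).
#' @param n_sim Number of simulated tiles.
#' @return A scalar threshold.
#' @export
default_risk_threshold <- function(config, n_sim = 2000) {
  with_seed(20200106, {
    P <- config$pois_per_tile; Tw <- config$n_weeks
    w <- config$category_weights; r0 <- config$visit_rate
    scores <- vapply(seq_len(n_sim), function(i) {
      m <- stats::rlnorm(10, 0, .INTENSITY_SDLOG)
      Fc <- numeric(10)
      for (p in seq_len(P)) {
        k <- if (stats::runif(1) < .P_TWO_CATEGORIES) 2L else 1L
        cats <- sample.int(10, k)
        f <- mean(stats::rpois(Tw, r0 * mean(m[cats])))
        Fc[cats] <- Fc[cats] + f
      }
      sum(w * Fc)
    }, numeric(1))
    stats::median(scores)
  })
}

# spherical destination point: from (lat, lng) degrees, bearing rad, dist km
destination_point <- function(lat, lng, bearing, dist_km) {
  r <- 6371
  phi1 <- lat * pi / 180; lam1 <- lng * pi / 180; d <- dist_km / r
  phi2 <- asin(sin(phi1) * cos(d) + cos(phi1) * sin(d) * cos(bearing))
  lam2 <- lam1 + atan2(sin(bearing) * sin(d) * cos(phi1),
                       cos(d) - sin(phi1) * sin(phi2))
  data.frame(lat = phi2 * 180 / pi,
             lng = ((lam2 * 180 / pi + 180) %% 360) - 180)
}

# sample a POI description: 4 category terms + 1 venue-unique token
poi_description <- function(categories, unique_token) {
  vocab <- unlist(.category_vocab[categories], use.names = FALSE)
  terms <- sample(vocab, min(4L, length(vocab)))
  paste(c(terms, unique_token), collapse = " ")
}

#' Generate a controlled check-in stream for one POI
#'
#' Emits `n` check-ins of which exactly `round(n * match_fraction)` pass BOTH
#' splicing gates against this POI (similarity > 3.5 on the 0-10 scale,
#' distance < 3 km) and the rest violate at least one gate: either their text
#' is drawn from a disjoint non-food vocabulary (similarity 0) or they are
#' displaced more than 3 km away. Matching texts copy at least 60% of the
#' POI's description tokens, always including its venue-unique token.
#'
#' @param poi One-row POI data.frame (`poi_id`, `lat`, `lng`, `description`).
#' @param n Number of check-ins (>= 0).
#' @param match_fraction Fraction in `[0, 1]` passing both gates.
#' @param max_offset_km Maximum displacement of any emitted check-in from the
#'   POI (>= 0). Distance-gate violators are only generated when this exceeds
#'   3.2 km; matching check-ins stay within `min(max_offset_km, 0.1)` km.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param weeks Integer vector of candidate week indices for the timestamps.
#' @param users Character vector of user ids to sample from.
#' @return A check-in data.frame (`checkin_id`, `user_id`, `timestamp`, `lat`,
#'   `lng`, `text`) with `n` rows.
#' @export
generate_checkins_for_poi <- function(poi, n, match_fraction = 1.0,
                                      max_offset_km = 0.1, seed = NULL,
                                      weeks = 1L, users = "u001") {
  stop_if(n < 0, "n must be >= 0")
  stop_if(max_offset_km < 0, "max_offset_km must be >= 0")
  stop_if(match_fraction < 0 || match_fraction > 1,
          "match_fraction must be in [0, 1]")
  empty <- data.frame(checkin_id = character(0), user_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      lat = numeric(0), lng = numeric(0), text = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  with_seed(seed, {
    n <- as.integer(n)
    n_match <- as.integer(round(n * match_fraction))
    is_match <- c(rep(TRUE, n_match), rep(FALSE, n - n_match))
    desc_tokens <- names(tokenize(poi$description))
    uniq <- desc_tokens[grepl("^venue", desc_tokens)]
    if (!length(uniq)) uniq <- desc_tokens[length(desc_tokens)]
    others <- setdiff(desc_tokens, uniq)

    text <- character(n); dist <- numeric(n)
    can_violate_dist <- max_offset_km > 3.2
    for (i in seq_len(n)) {
      if (is_match[i]) {
        k <- sample(3:5, 1)
        text[i] <- paste(c(uniq, sample(others, min(k - 1, length(others)))),
                         collapse = " ")
        dist[i] <- stats::runif(1, 0, min(max_offset_km, 0.1))
      } else if (can_violate_dist && stats::runif(1) < 0.3) {
        # distance violator: text still names the venue, posted from afar
        text[i] <- paste(c(uniq, sample(others, 1)), collapse = " ")
        dist[i] <- stats::runif(1, 3.2, max_offset_km)
      } else {
        text[i] <- paste(sample(.mismatch_vocab, 3), collapse = " ")
        dist[i] <- stats::runif(1, 0, min(max_offset_km, 0.1))
      }
    }
    pos <- destination_point(poi$lat, poi$lng, stats::runif(n, 0, 2 * pi), dist)
    wk <- if (length(weeks) == 1) rep(weeks, n) else sample(weeks, n, replace = TRUE)
    secs <- floor(stats::runif(n, 0, 7 * 86400))
    ts <- as.POSIXct(week_origin(), tz = "UTC") + (wk - 1) * 7 * 86400 + secs
    data.frame(checkin_id = paste0("c_", poi$poi_id, "_", seq_len(n)),
               user_id = sample(users, n, replace = TRUE),
               timestamp = ts,
               lat = round(pos$lat, 6), lng = round(pos$lng, 6),
               text = text, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic world
#'
#' Builds the full synthetic study system: tiles sampled inside the bounding
#' box, POIs placed per tile with category labels and food-vocabulary
#' descriptions, a weekly check-in stream whose matched intensity per category
#' follows the tile's planted lognormal intensity, and Poisson case profiles
#' whose category mix mirrors the planted weights. The stored true tile score
#' is recomputed from the emitted records by running the actual splicing rules,
#' so with `noise_sd = 0` the label is an exact function of the emitted data.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world` with elements `pois`, `checkins`,
#'   `cases` (long data.frame `case_id`, `tile`, `week`, `category`, `count`),
#'   `truth` (data.frame `tile`, `score`, `label`), `tiles`, and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, {
    zoom <- config$zoom; bb <- config$bbox
    corner_sw <- tile_index(bb[1], bb[3], zoom)
    corner_ne <- tile_index(bb[2], bb[4], zoom)
    xs <- corner_sw$x:corner_ne$x
    ys <- corner_ne$y:corner_sw$y     # y grows southwards
    grid <- expand.grid(x = xs, y = ys)
    stop_if(nrow(grid) < config$n_tiles,
            "bbox too small for n_tiles at this zoom")
    pick <- grid[sample.int(nrow(grid), config$n_tiles), ]
    tiles <- data.frame(z = zoom, x = pick$x, y = pick$y,
                        tile = tile_key(zoom, pick$x, pick$y))
    tiles <- tiles[order(tiles$tile), ]
    rownames(tiles) <- NULL

    n_tiles <- config$n_tiles; P <- config$pois_per_tile
    intensity <- matrix(NA_real_, nrow = n_tiles, ncol = 10,
                        dimnames = list(tiles$tile, paste0("A", 1:10)))

    users <- sprintf("u%04d", seq_len(config$n_users))
    amenities <- c("restaurant", "cafe", "marketplace", "fast_food", "shop")
    cuisines <- c("american", "italian", "mexican", "asian", "regional", "")

    poi_list <- vector("list", n_tiles)
    checkin_list <- vector("list", n_tiles)
    inset <- 0.07
    for (ti in seq_len(n_tiles)) {
      b <- tile_bounds(tiles$z[ti], tiles$x[ti], tiles$y[ti])
      lat <- stats::runif(P, b$lat_min + inset * (b$lat_max - b$lat_min),
                          b$lat_max - inset * (b$lat_max - b$lat_min))
      lng <- stats::runif(P, b$lng_min + inset * (b$lng_max - b$lng_min),
                          b$lng_max - inset * (b$lng_max - b$lng_min))
      ids <- sprintf("poi_%03d_%02d", ti, seq_len(P))
      cats <- vapply(seq_len(P), function(i) {
        k <- if (stats::runif(1) < .P_TWO_CATEGORIES) 2L else 1L
        paste(sort(paste0("A", sample.int(10, k))), collapse = ",")
      }, character(1))
      desc <- vapply(seq_len(P), function(i) {
        poi_description(strsplit(cats[i], ",")[[1]], paste0("venue", ti, "x", i))
      }, character(1))

      # planted separation: redraw the tile's category intensity until its
      # expected structural score clears the margin around the threshold
      cat_sets <- strsplit(cats, ",", fixed = TRUE)
      w <- config$category_weights
      expected_score <- function(m) {
        lam <- vapply(cat_sets, function(cs) config$visit_rate * mean(m[match(cs, paste0("A", 1:10))]),
                      numeric(1))
        sum(vapply(1:10, function(c) {
          w[c] * sum(lam[vapply(cat_sets, function(cs) paste0("A", c) %in% cs,
                                logical(1))])
        }, numeric(1)))
      }
      margin <- config$margin_frac * abs(config$risk_threshold)
      for (try in seq_len(500)) {
        m <- stats::rlnorm(10, 0, .INTENSITY_SDLOG)
        if (abs(expected_score(m) - config$risk_threshold) >= margin) break
      }
      intensity[ti, ] <- m
      pois <- data.frame(poi_id = ids, lat = round(lat, 6), lng = round(lng, 6),
                         tile = tiles$tile[ti],
                         name = paste("Venue", ti, seq_len(P)),
                         description = desc, categories = cats,
                         amenity = sample(amenities, P, replace = TRUE),
                         cuisine = sample(cuisines, P, replace = TRUE),
                         stringsAsFactors = FALSE)
      poi_list[[ti]] <- pois

      per_poi <- vector("list", P)
      mf <- config$match_fraction
      for (i in seq_len(P)) {
        pcats <- strsplit(cats[i], ",")[[1]]
        lam <- config$visit_rate * mean(intensity[ti, pcats])
        m_t <- stats::rpois(config$n_weeks, lam)
        x_t <- if (mf > 0 && mf < 1) {
          stats::rpois(config$n_weeks, lam * (1 - mf) / mf)
        } else if (mf == 0) stats::rpois(config$n_weeks, lam) else 0L
        per_week <- vector("list", config$n_weeks)
        for (t in seq_len(config$n_weeks)) {
          nt <- m_t[t] + (if (length(x_t) > 1) x_t[t] else x_t)
          if (mf == 0) nt <- x_t[t]
          if (nt == 0) next
          frac <- if (mf == 0) 0 else m_t[t] / nt
          per_week[[t]] <- generate_checkins_for_poi(
            pois[i, ], nt, match_fraction = frac, max_offset_km = 8,
            seed = NULL, weeks = t, users = users)
        }
        per_week <- per_week[!vapply(per_week, is.null, logical(1))]
        if (length(per_week)) per_poi[[i]] <- do.call(rbind, per_week)
      }
      per_poi <- per_poi[!vapply(per_poi, is.null, logical(1))]
      if (length(per_poi)) checkin_list[[ti]] <- do.call(rbind, per_poi)
    }
    pois <- do.call(rbind, poi_list)
    checkins <- do.call(rbind, checkin_list)
    rownames(pois) <- rownames(checkins) <- NULL
    checkins$checkin_id <- sprintf("chk_%06d", seq_len(nrow(checkins)))

    # case profiles: Poisson weekly category counts, rates proportional to the
    # planted weights times the tile intensity
    case_tile <- sample(tiles$tile, config$n_cases, replace = TRUE)
    case_rows <- vector("list", config$n_cases)
    w <- config$category_weights
    for (ci in seq_len(config$n_cases)) {
      q <- w * intensity[case_tile[ci], ]
      q <- if (sum(q) > 0) q / sum(q) else rep(0.1, 10)
      rates <- config$case_visits_per_week * q
      counts <- matrix(stats::rpois(10 * config$n_weeks, rates),
                       nrow = 10)  # categories x weeks (rates recycle by row)
      nz <- which(counts > 0, arr.ind = TRUE)
      if (nrow(nz) == 0) next
      case_rows[[ci]] <- data.frame(
        case_id = sprintf("case_%04d", ci), tile = case_tile[ci],
        week = as.integer(nz[, 2]), category = paste0("A", nz[, 1]),
        count = as.integer(counts[nz]), stringsAsFactors = FALSE)
    }
    case_rows <- case_rows[!vapply(case_rows, is.null, logical(1))]
    cases <- do.call(rbind, case_rows)
    cases <- cases[order(cases$case_id, cases$week, cases$category), ]
    rownames(cases) <- NULL

    # true score: actual splicing of the emitted records, tile by tile
    ck_tiles <- tile_key(zoom, tile_index(checkins$lat, checkins$lng, zoom)$x,
                         tile_index(checkins$lat, checkins$lng, zoom)$y)
    score <- numeric(n_tiles)
    for (ti in seq_len(n_tiles)) {
      tp <- pois[pois$tile == tiles$tile[ti], ]
      tc <- checkins[ck_tiles == tiles$tile[ti], ]
      fv <- build_feature_vectors(tp, tc, splice_params(), tile = tiles$tile[ti],
                                  n_weeks = config$n_weeks)
      Fc <- as.numeric(t(fv$onehot) %*% rowMeans(fv$freq))
      score[ti] <- sum(w * Fc)
    }
    if (config$noise_sd > 0) {
      score <- score + stats::rnorm(n_tiles, 0, config$noise_sd)
    }
    truth <- data.frame(tile = tiles$tile, score = score,
                        label = as.integer(score > config$risk_threshold))
    structure(list(pois = pois, checkins = checkins, cases = cases,
                   truth = truth, tiles = tiles, config = config),
              class = "synthetic_world")
  })
}

#' Noise level producing a target label-flip rate
#'
#' Given a noiseless world, finds the Gaussian score-noise standard deviation
#' at which regenerating the world (same seed, `noise_sd` set) flips the
#' labels of exactly `round(rate * n_tiles)` tiles. Because the noise draw is
#' the last RNG consumption of the generator, the standardised per-tile noise
#' is identical across `noise_sd` values, so each tile has a critical noise
#' level and the target count can be hit exactly (method `"realized"`).
#' Method `"expected"` instead solves for the expected flip fraction in
#' closed form.
#'
#' @param world A `synthetic_world` generated with `noise_sd = 0`.
#' @param rate Target flip fraction in (0, 0.5).
#' @param method `"realized"` (exact count; regenerates the world once
#'   internally) or `"expected"`.
#' @return A scalar noise standard deviation.
#' @export
noise_sd_for_flip_rate <- function(world, rate = 0.1,
                                   method = c("realized", "expected")) {
  method <- match.arg(method)
  stop_if(rate <= 0 || rate >= 0.5, "rate must be in (0, 0.5)")
  gap <- world$truth$score - world$config$risk_threshold
  if (method == "expected") {
    return(stats::uniroot(function(s) mean(stats::pnorm(-abs(gap) / s)) - rate,
                          c(1e-6, 1e3))$root)
  }
  cfg1 <- world$config
  cfg1$noise_sd <- 1
  z <- generate_world(cfg1)$truth$score - world$truth$score
  opposing <- sign(z) == -sign(gap) & z != 0
  crit <- sort(abs(gap[opposing]) / abs(z[opposing]))
  k <- round(rate * nrow(world$truth))
  stop_if(k < 1 || k > length(crit),
          "target flip count not reachable for this world")
  upper <- if (k < length(crit)) crit[k + 1] else crit[k] * 1.1
  (crit[k] + upper) / 2
}

#' Permute the planted tile labels of prepared data
#'
#' Shuffles the (label, score) pairs across tiles — the label-permutation null:
#' a model trained on permuted labels should predict held-out tiles no better
#' than chance.
#'
#' @param prepared A `glstm_data` object from [prepare_tiles()].
#' @param seed Integer seed for the permutation.
#' @return The `glstm_data` with permuted labels/scores.
#' @export
permute_tile_labels <- function(prepared, seed = 1) {
  stopifnot(inherits(prepared, "glstm_data"))
  n <- length(prepared$tiles)
  perm <- with_seed(seed, sample.int(n))
  labs <- vapply(prepared$tiles, function(t) t$label, numeric(1))[perm]
  scs <- vapply(prepared$tiles, function(t) t$score, numeric(1))[perm]
  for (i in seq_len(n)) {
    prepared$tiles[[i]]$label <- labs[i]
    prepared$tiles[[i]]$score <- scs[i]
  }
  prepared
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic food-access world\n")
  cat(sprintf("  tiles: %d (zoom %d)   POIs: %d   check-ins: %d   cases: %d\n",
              nrow(x$truth), x$config$zoom, nrow(x$pois), nrow(x$checkins),
              length(unique(x$cases$case_id))))
  cat(sprintf("  weeks: %d   risk threshold: %.3f   positive tiles: %d/%d\n",
              x$config$n_weeks, x$config$risk_threshold,
              sum(x$truth$label), nrow(x$truth)))
  invisible(x)
}
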