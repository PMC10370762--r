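# Feature splicing: join check-ins to POIs by text similarity and haversine
# distance, then count weekly visit frequencies. This is the step that turns a
# raw geotagged post stream into per-POI spatio-temporal features.

#' Splicing parameters
#'
#' Thresholds for joining a check-in to a POI: a text similarity score above
#' `sim_threshold` (strict) on the 0-10 scale AND a haversine distance below
#' `dist_threshold_km` (strict). Defaults are the gates of the underlying
#' model: similarity > 3.5, distance < 3 km.
#'
#' @param sim_threshold Similarity gate on the 0-`scale_max` scale.
#' @param dist_threshold_km Distance gate in km.
#' @param scale_max Upper end of the similarity/coordinate scale (10).
#' @return A list of class `splice_params`.
#' @export
splice_params <- function(sim_threshold = 3.5, dist_threshold_km = 3.0,
                          scale_max = 10) {
  stop_if(sim_threshold <= 0 || dist_threshold_km <= 0,
          "thresholds must be positive")
  stop_if(sim_threshold >= scale_max, "sim_threshold must be below scale_max")
  structure(list(sim_threshold = sim_threshold,
                 dist_threshold_km = dist_threshold_km,
                 scale_max = scale_max),
            class = "splice_params")
}

#' Tokenize free text into a term-frequency vector
#'
#' Lowercases, splits on non-alphanumeric runs, and counts terms.
#'
#' @param text A character scalar.
#' @return Named integer vector of term frequencies (possibly empty).
#' @export
#' @examples
#' tokenize("A nice hamburger, a NICE shake")
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(stats::setNames(integer(0), character(0)))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(stats::setNames(integer(0), character(0)))
  tab <- table(toks)
  stats::setNames(as.integer(tab), names(tab))
}

#' Text similarity on the 0-10 scale
#'
#' Cosine similarity between two term-frequency vectors, rescaled to 0-10
#' (`100% x 0.1`). Returns 0 when either vector is all-zero or empty.
#'
#' @param p,n Named nonnegative term-frequency vectors (names are terms).
#' @return A number in `[0, 10]`.
#' @export
#' @examples
#' similarity(c(burger = 1, fries = 1), c(burger = 1)) # 10/sqrt(2)
similarity <- function(p, n) {
  stop_if(any(p < 0) || any(n < 0), "term frequencies must be nonnegative")
  if (!length(p) || !length(n)) return(0)
  shared <- intersect(names(p), names(n))
  np <- sqrt(sum(p^2)); nn <- sqrt(sum(n^2))
  if (np == 0 || nn == 0) return(0)
  10 * sum(p[shared] * n[shared]) / (np * nn)
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised and symmetric.
#'
#' @param lat1,lng1,lat2,lng2 Coordinates in degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree along the equator, ~111.195 km
haversine_km <- function(lat1, lng1, lat2, lng2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlng <- (lng2 - lng1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlng / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

#' Match one check-in to the best qualifying POI
#'
#' Among candidate POIs whose similarity with the check-in text exceeds the
#' similarity gate (strict) and whose distance is under the distance gate
#' (strict), returns the id of the most similar one. Ties break to the nearest
#' POI, then to the lexicographically smallest `poi_id`.
#'
#' @param checkin A one-row check-in data.frame (needs `text`, `lat`, `lng`),
#'   or a list with those fields.
#' @param candidates POI data.frame (needs `poi_id`, `lat`, `lng`,
#'   `description`), normally the POIs of the check-in's map tile.
#' @param params A [splice_params()] object.
#' @return The matched `poi_id`, or `NA_character_` if no candidate qualifies.
#' @export
match_checkin <- function(checkin, candidates, params = splice_params()) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NA_character_)
  n_tokens <- tokenize(checkin$text)
  sims <- vapply(candidates$description,
                 function(d) similarity(tokenize(d), n_tokens), numeric(1),
                 USE.NAMES = FALSE)
  dists <- haversine_km(checkin$lat, checkin$lng, candidates$lat, candidates$lng)
  ok <- sims > params$sim_threshold & dists < params$dist_threshold_km
  if (!any(ok)) return(NA_character_)
  idx <- which(ok)
  idx <- idx[order(-sims[idx], dists[idx], candidates$poi_id[idx])]
  candidates$poi_id[idx[1]]
}

#' Weekly visit frequency of a POI
#'
#' Counts, per week `t`, the check-ins that pass both splicing gates against
#' this POI (strict inequalities). This is the per-POI frequency series the
#' temporal model consumes.
#'
#' @param poi One-row POI data.frame (needs `lat`, `lng`, `description`).
#' @param checkins Check-in data.frame (needs `timestamp`, `lat`, `lng`, `text`).
#' @param params A [splice_params()] object.
#' @param n_weeks Length of the returned series; defaults to the largest week
#'   index seen in `checkins` (1 if none qualify).
#' @return Integer vector `f[t]`, `t = 1..n_weeks`.
#' @export
weekly_visit_frequency <- function(poi, checkins, params = splice_params(),
                                   n_weeks = NULL) {
  wk <- week_index(checkins$timestamp)
  if (is.null(n_weeks)) n_weeks <- max(1L, wk, 0L)
  f <- integer(n_weeks)
  if (nrow(checkins) == 0) return(f)
  p_tokens <- tokenize(poi$description)
  dists <- haversine_km(poi$lat, poi$lng, checkins$lat, checkins$lng)
  near <- which(dists < params$dist_threshold_km & wk >= 1L & wk <= n_weeks)
  for (i in near) {
    if (similarity(p_tokens, tokenize(checkins$text[i])) > params$sim_threshold) {
      f[wk[i]] <- f[wk[i]] + 1L
    }
  }
  f
}

# Vectorised splicing of all check-ins in one tile against that tile's POIs.
# Builds term matrices over the union vocabulary so similarity is one matrix
# product; matching is argmax similarity among qualifying candidates with the
# documented tie-breaks. Returns the check-in frame with matched_poi,
# similarity and distance_km filled in.
splice_tile <- function(pois, checkins, params = splice_params()) {
  checkins$matched_poi <- rep(NA_character_, nrow(checkins))
  checkins$similarity <- rep(NA_real_, nrow(checkins))
  checkins$distance_km <- rep(NA_real_, nrow(checkins))
  if (nrow(pois) == 0 || nrow(checkins) == 0) return(checkins)

  ptoks <- lapply(pois$description, tokenize)
  ntoks <- lapply(checkins$text, tokenize)
  vocab <- unique(c(unlist(lapply(ptoks, names)), unlist(lapply(ntoks, names))))
  if (!length(vocab)) return(checkins)
  tf_matrix <- function(toklist) {
    m <- matrix(0, nrow = length(toklist), ncol = length(vocab))
    for (i in seq_along(toklist)) {
      tk <- toklist[[i]]
      if (length(tk)) m[i, match(names(tk), vocab)] <- tk
    }
    m
  }
  P <- tf_matrix(ptoks)                       # pois x vocab
  N <- tf_matrix(ntoks)                       # checkins x vocab
  pn <- sqrt(rowSums(P^2)); nn <- sqrt(rowSums(N^2))
  pn[pn == 0] <- Inf; nn[nn == 0] <- Inf
  S <- 10 * (N %*% t(P)) / outer(nn, pn)      # checkins x pois, 0..10
  D <- outer(seq_len(nrow(checkins)), seq_len(nrow(pois)),
             function(i, j) haversine_km(checkins$lat[i], checkins$lng[i],
                                         pois$lat[j], pois$lng[j]))
  ok <- S > params$sim_threshold & D < params$dist_threshold_km
  hit <- which(rowSums(ok) > 0)
  for (i in hit) {
    idx <- which(ok[i, ])
    idx <- idx[order(-S[i, idx], D[i, idx], pois$poi_id[idx])]
    j <- idx[1]
    checkins$matched_poi[i] <- pois$poi_id[j]
    checkins$similarity[i] <- S[i, j]
    checkins$distance_km[i] <- D[i, j]
  }
  checkins
}

#' Per-tile POI feature vectors
#'
#' Builds the node-feature payload for one tile: coordinates min-max scaled to
#' `[0, scale_max]` within the tile's bounding box, the 10-way category
#' one-hot, and the weekly visit-frequency series from spliced check-ins
#' (one check-in is matched to at most one POI, by [match_checkin()]'s rule).
#'
#' @param pois POIs of one tile (data.frame with `poi_id`, `lat`, `lng`,
#'   `description`, `categories`, `tile`).
#' @param checkins Check-ins to splice (any subset; only those matching these
#'   POIs are counted).
#' @param params A [splice_params()] object.
#' @param tile Tile key `"z/x/y"` giving the scaling bbox; if `NULL`, the POI
#'   bounding box is used (a degenerate box scales to 0 with a warning).
#' @param n_weeks Number of weekly bins `T`.
#' @return A list of class `poi_features`: `poi_id`, `tile`, `scaled` (n x 2),
#'   `onehot` (n x 10), `freq` (n x T), `coords` (n x 2 raw lat/lng),
#'   `categories` (list), `n_weeks`.
#' @export
build_feature_vectors <- function(pois, checkins, params = splice_params(),
                                  tile = NULL, n_weeks = NULL) {
  stop_if(nrow(pois) == 0, "no POIs in tile")
  ord <- order(pois$poi_id)
  pois <- pois[ord, , drop = FALSE]
  wk <- week_index(checkins$timestamp)
  if (is.null(n_weeks)) n_weeks <- max(1L, wk, 0L)

  spliced <- splice_tile(pois, checkins, params)
  freq <- matrix(0L, nrow = nrow(pois), ncol = n_weeks,
                 dimnames = list(pois$poi_id, NULL))
  keep <- !is.na(spliced$matched_poi) & wk >= 1L & wk <= n_weeks
  if (any(keep)) {
    tab <- table(factor(spliced$matched_poi[keep], levels = pois$poi_id),
                 factor(wk[keep], levels = seq_len(n_weeks)))
    freq <- matrix(as.integer(tab), nrow = nrow(pois),
                   dimnames = list(pois$poi_id, NULL))
  }

  if (!is.null(tile)) {
    tk <- parse_tile_key(tile)
    bb <- tile_bounds(tk$z, tk$x, tk$y)
    rng_lat <- c(bb$lat_min, bb$lat_max); rng_lng <- c(bb$lng_min, bb$lng_max)
  } else {
    rng_lat <- range(pois$lat); rng_lng <- range(pois$lng)
  }
  if (diff(rng_lat) <= 0 || diff(rng_lng) <= 0) {
    warning("degenerate bounding box; scaled coordinates set to 0")
  }
  scale1 <- function(v, rng) {
    if (diff(rng) <= 0) return(rep(0, length(v)))
    params$scale_max * (v - rng[1]) / diff(rng)
  }
  scaled <- cbind(lat = scale1(pois$lat, rng_lat), lng = scale1(pois$lng, rng_lng))

  cats <- strsplit(pois$categories, ",", fixed = TRUE)
  onehot <- matrix(0, nrow = nrow(pois), ncol = 10,
                   dimnames = list(pois$poi_id, paste0("A", 1:10)))
  for (i in seq_along(cats)) onehot[i, cats[[i]]] <- 1

  structure(list(poi_id = pois$poi_id,
                 tile = if (is.null(tile)) unique(pois$tile)[1] else tile,
                 scaled = scaled, onehot = onehot, freq = freq,
                 coords = cbind(lat = pois$lat, lng = pois$lng),
                 categories = cats, n_weeks = n_weeks),
            class = "poi_features")
}

# node feature matrix at week t:
# [scaled lat, scaled lng, onehot A1..A10, f^t, onehot * f^t]
# The last block resolves the visit frequency by category, the quantity the
# risk model is about.
feature_matrix_at <- function(features, week) {
  f <- features$freq[, week]
  X <- cbind(features$scaled, features$onehot, freq = f,
             features$onehot * f)
  colnames(X)[14:23] <- paste0("f_A", 1:10)
  rownames(X) <- features$poi_id
  X
}
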