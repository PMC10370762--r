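# Shared in-code fixtures: small worlds and hand-built records.

tiny_world_config <- function(seed = 42, ...) {
  world_config(n_tiles = 6, pois_per_tile = 8, n_users = 30, n_cases = 24,
               n_weeks = 4, seed = seed, ...)
}

make_poi <- function(poi_id = "p1", lat = 40.7, lng = -74.0,
                     description = "burger fries venue1x1 pizza shake",
                     categories = "A8", tile = NULL, name = "Test venue") {
  if (is.null(tile)) {
    ti <- tile_index(lat, lng, 14)
    tile <- tile_key(ti$z, ti$x, ti$y)
  }
  data.frame(poi_id = poi_id, lat = lat, lng = lng, tile = tile, name = name,
             description = description, categories = categories,
             amenity = "fast_food", cuisine = "american",
             stringsAsFactors = FALSE)
}

make_checkin <- function(checkin_id = "c1", lat = 40.7, lng = -74.0,
                         text = "burger venue1x1", week = 1,
                         user_id = "u1") {
  ts <- as.POSIXct("2020-01-06", tz = "UTC") + (week - 1) * 7 * 86400 + 3600
  data.frame(checkin_id = checkin_id, user_id = user_id, timestamp = ts,
             lat = lat, lng = lng, text = text, stringsAsFactors = FALSE)
}

# brute-force weekly frequency: the 5-line oracle the module must reproduce
oracle_weekly_frequency <- function(poi, checkins, sim_thr = 3.5, dist_thr = 3,
                                    n_weeks) {
  f <- integer(n_weeks)
  for (i in seq_len(nrow(checkins))) {
    s <- similarity(tokenize(poi$description), tokenize(checkins$text[i]))
    d <- haversine_km(poi$lat, poi$lng, checkins$lat[i], checkins$lng[i])
    t <- week_index(checkins$timestamp[i])
    if (s > sim_thr && d < dist_thr && t >= 1 && t <= n_weeks) f[t] <- f[t] + 1L
  }
  f
}
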