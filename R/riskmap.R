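# Geographically weighted risk surfaces: a Gaussian-kernel local aggregation
# of per-POI scores into a categories-by-regions matching matrix, and the
# four-layer GeoJSON map export.

#' Gaussian geographic kernel weights
#'
#' `w_i = exp(-(d_i / bandwidth)^2)` with `d_i` the haversine distance from
#' center `i` to the query point, normalized to sum to 1. Weight decays
#' monotonically with distance.
#'
#' @param centers Matrix or data.frame of `(lat, lng)` rows.
#' @param query A `(lat, lng)` pair.
#' @param bandwidth_km Kernel bandwidth in km (> 0; default 3 km, matching the
#'   splicing distance gate).
#' @return A probability vector over the centers.
#' @export
geographic_weights <- function(centers, query, bandwidth_km = 3) {
  stop_if(bandwidth_km <= 0, "bandwidth must be positive")
  centers <- as.matrix(centers)
  stop_if(nrow(centers) == 0, "empty centers")
  d <- haversine_km(centers[, 1], centers[, 2], query[1], query[2])
  w <- exp(-(d / bandwidth_km)^2)
  if (sum(w) == 0) w <- rep(1, length(w)) # all centers far: fall back to uniform
  w / sum(w)
}

#' Category-by-region spatial weight matrix
#'
#' Entry `(c, r)` is the geographic-kernel-weighted mean of the predicted
#' scores of category-`c` POIs in region `r`, with the kernel centred on the
#' region's centroid. Darker (higher) values mean the local visit behaviour is
#' more consistent with case food-access behaviour. Regions with no POI of a
#' category get `NA`, not zero.
#'
#' @param poi_scores data.frame with `poi_id` and `score` (e.g. from
#'   `predict(model, unit = "poi")`).
#' @param pois POI data.frame (`poi_id`, `lat`, `lng`, `tile`, `categories`).
#' @param regions Character vector of region ids (default: the POIs' tiles).
#'   Regions are slippy tile keys; each POI belongs to its `tile`.
#' @param bandwidth_km Kernel bandwidth in km.
#' @return A `10 x length(regions)` matrix, rows `A1..A10`.
#' @export
category_weight_matrix <- function(poi_scores, pois, regions = NULL,
                                   bandwidth_km = 3) {
  regions <- regions %||% sort(unique(pois$tile))
  m <- matrix(NA_real_, 10, length(regions),
              dimnames = list(paste0("A", 1:10), regions))
  score <- poi_scores$score[match(pois$poi_id, poi_scores$poi_id)]
  cats <- strsplit(pois$categories, ",", fixed = TRUE)
  for (r in seq_along(regions)) {
    in_r <- which(pois$tile == regions[r] & !is.na(score))
    if (!length(in_r)) next
    tk <- parse_tile_key(regions[r])
    ctr <- tile_center(tk$z, tk$x, tk$y)
    for (c in 1:10) {
      cat_c <- in_r[vapply(cats[in_r], function(cs) paste0("A", c) %in% cs,
                           logical(1))]
      if (!length(cat_c)) next
      w <- geographic_weights(cbind(pois$lat[cat_c], pois$lng[cat_c]),
                              c(ctr$lat, ctr$lng), bandwidth_km)
      m[c, r] <- sum(w * score[cat_c])
    }
  }
  m
}

#' Assemble a risk surface
#'
#' Bundles per-tile risk scores with the category spatial weight matrix for
#' map export.
#'
#' @param tile_scores data.frame `tile`, `score`, `label` (e.g. from
#'   [predict.glstm()]).
#' @param poi_scores data.frame `poi_id`, `score` from
#'   `predict(model, unit = "poi")`.
#' @param pois POI data.frame.
#' @param bandwidth_km Kernel bandwidth in km.
#' @return A list of class `risk_surface`: `tiles`, `scores`, `labels`,
#'   `category_matrix`, `kernel_bandwidth_km`.
#' @export
risk_surface <- function(tile_scores, poi_scores, pois, bandwidth_km = 3) {
  stop_if(nrow(tile_scores) == 0, "empty surface")
  ord <- order(tile_scores$tile)
  tile_scores <- tile_scores[ord, , drop = FALSE]
  cm <- category_weight_matrix(poi_scores, pois,
                               regions = tile_scores$tile,
                               bandwidth_km = bandwidth_km)
  structure(list(tiles = tile_scores$tile, scores = tile_scores$score,
                 labels = tile_scores$label, category_matrix = cm,
                 kernel_bandwidth_km = bandwidth_km),
            class = "risk_surface")
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf("Risk surface: %d tiles, bandwidth %.1f km, %d flagged\n",
              length(x$tiles), x$kernel_bandwidth_km, sum(x$labels)))
  invisible(x)
}

#' Export the four-layer map visualization
#'
#' Writes four GeoJSON FeatureCollections into a directory, bottom to top:
#' `layer1_boundaries.geojson` (tile boundary rectangles),
#' `layer2_checkins.geojson` (check-in points), `layer3_pois.geojson` (POI
#' points with categories and attributes), and `layer4_risk.geojson` (tile
#' polygons with risk scores — the heatmap layer). Feature ordering is
#' deterministic, so a fixed world and surface re-export byte-identically.
#'
#' @param world A `synthetic_world` (or list with `pois`, `checkins`).
#' @param surface A [risk_surface()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the four paths, invisibly.
#' @export
export_layers <- function(world, surface, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("layer1_boundaries.geojson",
                                "layer2_checkins.geojson",
                                "layer3_pois.geojson",
                                "layer4_risk.geojson"))
  tiles <- sort(unique(world$pois$tile))
  feats1 <- vapply(tiles, function(tid) {
    tk <- parse_tile_key(tid)
    feature_bbox_polygon(tile_bounds(tk$z, tk$x, tk$y),
                         props_json(tile = json_str(tid)))
  }, character(1))
  write_feature_collection(feats1, paths[1])

  ck <- world$checkins[order(world$checkins$checkin_id), , drop = FALSE]
  feats2 <- feature_point(ck$lng, ck$lat,
                          props_json(checkin_id = json_str(ck$checkin_id),
                                     user_id = json_str(ck$user_id),
                                     timestamp = json_str(fmt_time(ck$timestamp))))
  write_feature_collection(feats2, paths[2])

  write_pois_geojson(world$pois, paths[3])
  write_risk_geojson(surface, paths[4])
  invisible(paths)
}
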