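# Slippy-map (z/x/y, Web Mercator) tile indexing. Tiles are the spatial unit
# the model trains on: one tile = one graph.

MAX_MERCATOR_LAT <- 85.05112878

#' Slippy-map tile index of a coordinate
#'
#' Standard Web Mercator tile arithmetic:
#' `x = floor((lng+180)/360 * 2^z)`,
#' `y = floor((1 - asinh(tan(lat))/pi)/2 * 2^z)`.
#' Longitude is taken on `[-180, 180)`; `lng = 180` wraps to the west edge.
#'
#' @param lat,lng Coordinates in degrees (WGS84). Vectorised.
#' @param zoom Integer zoom level (0-22).
#' @return A data.frame with integer columns `z`, `x`, `y`.
#' @seealso [tile_bounds()], the inverse on tile corners.
#' @export
#' @examples
#' tile_index(0, 0, zoom = 1) # x = 1, y = 1
tile_index <- function(lat, lng, zoom) {
  stop_if(any(abs(lat) > MAX_MERCATOR_LAT),
          "latitude outside Web Mercator range (|lat| <= 85.0511)")
  stop_if(zoom < 0 || zoom != round(zoom), "zoom must be a nonnegative integer")
  n <- 2^zoom
  lng <- ((lng + 180) %% 360) - 180 # wrap into [-180, 180)
  x <- floor((lng + 180) / 360 * n)
  phi <- lat * pi / 180
  y <- floor((1 - asinh(tan(phi)) / pi) / 2 * n)
  data.frame(z = as.integer(zoom),
             x = as.integer(pmin(pmax(x, 0), n - 1)),
             y = as.integer(pmin(pmax(y, 0), n - 1)))
}

#' Geographic bounds of a slippy tile
#'
#' Inverse of [tile_index()]: the tile's bounding box in degrees. Tiles are
#' half-open in x/y (west and north edges inclusive), so a point on a shared
#' edge belongs to exactly one tile.
#'
#' @param z,x,y Tile coordinates (vectorised); `0 <= x, y < 2^z`.
#' @return A data.frame with columns `lat_min`, `lat_max`, `lng_min`, `lng_max`.
#' @export
#' @examples
#' tile_bounds(0, 0, 0) # the whole world
tile_bounds <- function(z, x, y) {
  stop_if(any(x < 0 | y < 0 | x >= 2^z | y >= 2^z), "tile x/y out of range for zoom")
  n <- 2^z
  lng_min <- x / n * 360 - 180
  lng_max <- (x + 1) / n * 360 - 180
  lat_max <- atan(sinh(pi * (1 - 2 * y / n))) * 180 / pi
  lat_min <- atan(sinh(pi * (1 - 2 * (y + 1) / n))) * 180 / pi
  data.frame(lat_min = lat_min, lat_max = lat_max,
             lng_min = lng_min, lng_max = lng_max)
}

#' @rdname tile_index
#' @param key Tile key string(s) `"z/x/y"`.
#' @export
tile_key <- function(z, x, y) sprintf("%d/%d/%d", as.integer(z), as.integer(x), as.integer(y))

#' @rdname tile_index
#' @export
parse_tile_key <- function(key) {
  parts <- do.call(rbind, strsplit(key, "/", fixed = TRUE))
  stop_if(ncol(parts) != 3, "tile key must be 'z/x/y'")
  out <- data.frame(z = as.integer(parts[, 1]), x = as.integer(parts[, 2]),
                    y = as.integer(parts[, 3]))
  stop_if(anyNA(out), "malformed tile key")
  stop_if(any(out$x < 0 | out$y < 0 | out$x >= 2^out$z | out$y >= 2^out$z),
          "tile x/y out of range for zoom")
  out
}

# centroid of tiles (used as the query point for geographic weighting)
tile_center <- function(z, x, y) {
  b <- tile_bounds(z, x, y)
  data.frame(lat = (b$lat_min + b$lat_max) / 2, lng = (b$lng_min + b$lng_max) / 2)
}
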