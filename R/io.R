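# Readers and writers for the pipeline's formats: POIs as GeoJSON
# FeatureCollections, check-ins as JSON-lines, cases and truth as CSV.
# Writers format numbers deterministically so identical inputs give
# byte-identical files; internal coordinate order is (lat, lng), GeoJSON
# order on disk is [lng, lat].

json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

json_str <- function(x) ifelse(is.na(x), "null", paste0("\"", json_escape(x), "\""))

props_json <- function(...) {
  kv <- list(...) # vectorised: each argument may be a vector of equal length
  parts <- Map(function(nm, v) sprintf("\"%s\":%s", nm, v), names(kv), kv)
  paste0("{", do.call(paste, c(parts, sep = ",")), "}")
}

feature_point <- function(lng, lat, props) {
  sprintf("{\"type\":\"Feature\",\"geometry\":{\"type\":\"Point\",\"coordinates\":[%s,%s]},\"properties\":%s}",
          fmt_num(lng), fmt_num(lat), props)
}

feature_bbox_polygon <- function(b, props) {
  ring <- sprintf("[[%s,%s],[%s,%s],[%s,%s],[%s,%s],[%s,%s]]",
                  fmt_num(b$lng_min), fmt_num(b$lat_min),
                  fmt_num(b$lng_max), fmt_num(b$lat_min),
                  fmt_num(b$lng_max), fmt_num(b$lat_max),
                  fmt_num(b$lng_min), fmt_num(b$lat_max),
                  fmt_num(b$lng_min), fmt_num(b$lat_min))
  sprintf("{\"type\":\"Feature\",\"geometry\":{\"type\":\"Polygon\",\"coordinates\":[%s]},\"properties\":%s}",
          ring, props)
}

write_feature_collection <- function(features, path) {
  writeLines(c("{\"type\":\"FeatureCollection\",\"features\":[",
               paste0(features, c(rep(",", max(0, length(features) - 1)), "")),
               "]}"), path)
  invisible(path)
}

#' Write POIs as GeoJSON
#'
#' @param pois POI data.frame (`poi_id`, `lat`, `lng`, `tile`, `name`,
#'   `description`, `categories`, optional `amenity`, `cuisine`).
#' @param path Output `.geojson` path.
#' @return The path, invisibly.
#' @export
write_pois_geojson <- function(pois, path) {
  pois <- pois[order(pois$poi_id), , drop = FALSE]
  feats <- vapply(seq_len(nrow(pois)), function(i) {
    p <- pois[i, ]
    feature_point(p$lng, p$lat, props_json(
      poi_id = json_str(p$poi_id), name = json_str(p$name),
      description = json_str(p$description), categories = json_str(p$categories),
      tile = json_str(p$tile),
      amenity = json_str(if ("amenity" %in% names(p)) p$amenity else NA),
      cuisine = json_str(if ("cuisine" %in% names(p)) p$cuisine else NA)))
  }, character(1))
  write_feature_collection(feats, path)
}

#' Write check-ins as JSON-lines
#'
#' @param checkins Check-in data.frame (`checkin_id`, `user_id`, `timestamp`,
#'   `lat`, `lng`, `text`).
#' @param path Output `.jsonl` path.
#' @return The path, invisibly.
#' @export
write_checkins_jsonl <- function(checkins, path) {
  checkins <- checkins[order(checkins$checkin_id), , drop = FALSE]
  lines <- sprintf(
    "{\"checkin_id\":%s,\"user_id\":%s,\"timestamp\":%s,\"lat\":%s,\"lng\":%s,\"text\":%s}",
    json_str(checkins$checkin_id), json_str(checkins$user_id),
    json_str(fmt_time(checkins$timestamp)), fmt_num(checkins$lat),
    fmt_num(checkins$lng), json_str(checkins$text))
  writeLines(lines, path)
  invisible(path)
}

#' Write case profiles / truth as CSV
#'
#' @param cases Long case data.frame (`case_id`, `tile`, `week`, `category`,
#'   `count`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cases_csv <- function(cases, path) {
  cases <- cases[order(cases$case_id, cases$week, cases$category), , drop = FALSE]
  writeLines(c("case_id,tile,week,category,count",
               sprintf("%s,%s,%d,%s,%d", cases$case_id, cases$tile,
                       as.integer(cases$week), cases$category,
                       as.integer(cases$count))), path)
  invisible(path)
}

#' @rdname write_cases_csv
#' @param truth Truth data.frame (`tile`, `score`, `label`).
#' @export
write_truth_csv <- function(truth, path) {
  truth <- truth[order(truth$tile), , drop = FALSE]
  writeLines(c("tile,score,label",
               sprintf("%s,%s,%d", truth$tile, fmt_num(truth$score),
                       as.integer(truth$label))), path)
  invisible(path)
}

#' Write a synthetic world to fixture files
#'
#' Emits `pois.geojson`, `checkins.jsonl`, `cases.csv` and `truth.csv` into a
#' directory; the files round-trip losslessly through the package readers and
#' are byte-stable for a fixed world.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return A manifest data.frame (`file`, `n_records`, `md5`), invisibly the
#'   same.
#' @export
write_fixtures <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stop_if(file.access(dir, 2) != 0, "directory is not writable")
  paths <- file.path(dir, c("pois.geojson", "checkins.jsonl", "cases.csv",
                            "truth.csv"))
  write_pois_geojson(world$pois, paths[1])
  write_checkins_jsonl(world$checkins, paths[2])
  write_cases_csv(world$cases, paths[3])
  write_truth_csv(world$truth, paths[4])
  data.frame(file = basename(paths),
             n_records = c(nrow(world$pois), nrow(world$checkins),
                           nrow(world$cases), nrow(world$truth)),
             md5 = unname(tools::md5sum(paths)), stringsAsFactors = FALSE)
}

validate_coords <- function(lat, lng) {
  ok <- !is.na(lat) & !is.na(lng) & abs(lat) <= MAX_MERCATOR_LAT &
    lng >= -180 & lng < 180
  ok
}

report_rejects <- function(out, n_rejected, what) {
  if (n_rejected > 0) {
    message(sprintf("%s: rejected %d malformed record(s)", what, n_rejected))
  }
  attr(out, "rejected") <- n_rejected
  out
}

#' Read POIs from GeoJSON or CSV
#'
#' Records violating the type invariants (coordinates outside the Web Mercator
#' range, longitude outside `[-180, 180)`, empty categories) are rejected; the
#' rejection count is reported and attached as attribute `"rejected"`.
#'
#' @param path A `.geojson`/`.json` FeatureCollection or a `.csv` with columns
#'   `poi_id`, `lat`, `lng`, `tile`, `name`, `description`, `categories`.
#' @return POI data.frame.
#' @export
read_pois <- function(path) {
  stop_if(!file.exists(path), paste("no such file:", path))
  if (grepl("\\.(geojson|json)$", path)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    stop_if(!identical(gj$type, "FeatureCollection"), "not a FeatureCollection")
    props <- gj$features$properties
    coords <- do.call(rbind, gj$features$geometry$coordinates)
    need <- c("poi_id", "name", "description", "categories", "tile")
    missing_col <- setdiff(need, names(props))
    stop_if(length(missing_col) > 0,
            paste("missing mandatory column(s):", paste(missing_col, collapse = ", ")))
    out <- data.frame(poi_id = props$poi_id, lat = coords[, 2], lng = coords[, 1],
                      tile = props$tile, name = props$name,
                      description = props$description,
                      categories = props$categories,
                      amenity = props$amenity %||% NA_character_,
                      cuisine = props$cuisine %||% NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(lat = "numeric", lng = "numeric"))
    need <- c("poi_id", "lat", "lng", "tile", "name", "description", "categories")
    missing_col <- setdiff(need, names(out))
    stop_if(length(missing_col) > 0,
            paste("missing mandatory column(s):", paste(missing_col, collapse = ", ")))
  }
  ok <- validate_coords(out$lat, out$lng) & !is.na(out$categories) &
    nzchar(out$categories)
  report_rejects(out[ok, , drop = FALSE], sum(!ok), "read_pois")
}

#' Read check-ins from JSON-lines
#'
#' One JSON object per line with fields `checkin_id`, `user_id`, `timestamp`
#' (ISO-8601 UTC), `lat`, `lng`, `text`. Malformed lines and records violating
#' coordinate invariants are rejected and counted, not silently dropped.
#'
#' @param path A `.jsonl` path.
#' @return Check-in data.frame with attribute `"rejected"`.
#' @export
read_checkins <- function(path) {
  stop_if(!file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  bad_parse <- vapply(recs, is.null, logical(1))
  recs <- recs[!bad_parse]
  need <- c("checkin_id", "user_id", "timestamp", "lat", "lng", "text")
  has_fields <- vapply(recs, function(r) all(need %in% names(r)), logical(1))
  recs <- recs[has_fields]
  out <- data.frame(
    checkin_id = vapply(recs, function(r) as.character(r$checkin_id), character(1)),
    user_id = vapply(recs, function(r) as.character(r$user_id), character(1)),
    timestamp = as.POSIXct(vapply(recs, function(r) as.character(r$timestamp),
                                  character(1)),
                           tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ"),
    lat = vapply(recs, function(r) as.numeric(r$lat), numeric(1)),
    lng = vapply(recs, function(r) as.numeric(r$lng), numeric(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    stringsAsFactors = FALSE)
  ok <- validate_coords(out$lat, out$lng) & !is.na(out$timestamp)
  n_rej <- sum(bad_parse) + sum(!has_fields) + sum(!ok)
  report_rejects(out[ok, , drop = FALSE], n_rej, "read_checkins")
}

#' Read case profiles from CSV
#'
#' @param path CSV with columns `case_id`, `tile`, `week`, `category`, `count`.
#' @return Long case data.frame with attribute `"rejected"`.
#' @export
read_cases <- function(path) {
  stop_if(!file.exists(path), paste("no such file:", path))
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "tile", "week", "category", "count")
  missing_col <- setdiff(need, names(out))
  stop_if(length(missing_col) > 0,
          paste("missing mandatory column(s):", paste(missing_col, collapse = ", ")))
  ok <- out$category %in% paste0("A", 1:10) & !is.na(out$count) & out$count >= 0 &
    !is.na(out$week) & out$week >= 1
  report_rejects(out[ok, , drop = FALSE], sum(!ok), "read_cases")
}

#' Read truth labels from CSV
#'
#' @param path CSV with columns `tile`, `score`, `label`.
#' @return Truth data.frame.
#' @export
read_truth <- function(path) {
  stop_if(!file.exists(path), paste("no such file:", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML run configuration
#'
#' A light wrapper tying the fixture paths and model settings together:
#' fields `pois`, `checkins`, `cases`, `truth`, `zoom`, `n_weeks` plus any
#' model hyperparameters, resolved relative to the YAML file's directory.
#'
#' @param path YAML path.
#' @return Named list; path fields are made absolute.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in intersect(c("pois", "checkins", "cases", "truth"), names(cfg))) {
    if (!grepl("^/", cfg[[f]])) cfg[[f]] <- file.path(base, cfg[[f]])
  }
  cfg
}

#' Write a risk surface as GeoJSON
#'
#' One polygon feature per tile (the tile's bounding rectangle) with
#' properties `tile`, `risk_score`, `label` and the per-category weight column
#' of the surface's category matrix.
#'
#' @param surface A [risk_surface()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_risk_geojson <- function(surface, path) {
  stop_if(length(surface$tiles) == 0, "empty surface")
  ord <- order(surface$tiles)
  feats <- vapply(ord, function(i) {
    tid <- surface$tiles[i]
    tk <- parse_tile_key(tid)
    b <- tile_bounds(tk$z, tk$x, tk$y)
    cat_props <- surface$category_matrix[, i]
    cat_json <- paste(sprintf("\"%s\":%s", rownames(surface$category_matrix),
                              ifelse(is.na(cat_props), "null", fmt_num(cat_props))),
                      collapse = ",")
    props <- sprintf("{\"tile\":%s,\"risk_score\":%s,\"label\":%d,%s}",
                     json_str(tid), fmt_num(surface$scores[i]),
                     as.integer(surface$labels[i]), cat_json)
    feature_bbox_polygon(b, props)
  }, character(1))
  write_feature_collection(feats, path)
}
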