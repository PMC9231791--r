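#' Default POI category key list
#'
#' 53 amenity sub-keys grouped under the eight OSM amenity categories used
#' for walkability features (Sustenance, Education, Transportation,
#' Financial, Healthcare, Entertainment, Arts & Culture, Others). The exact
#' sub-key membership is a package default and fully configurable: any key
#' list can be passed to [extract_poi_features()].
#'
#' @return named character vector of length 53; names are the categories
#' @export
poi_keys <- function() {
  keys <- c(
    Sustenance = "restaurant", Sustenance = "cafe", Sustenance = "fast_food",
    Sustenance = "bar", Sustenance = "pub", Sustenance = "food_court",
    Sustenance = "ice_cream",
    Education = "school", Education = "kindergarten", Education = "college",
    Education = "university", Education = "library",
    Education = "language_school",
    Transportation = "bus_station", Transportation = "bicycle_parking",
    Transportation = "bicycle_rental", Transportation = "car_rental",
    Transportation = "charging_station", Transportation = "fuel",
    Transportation = "parking", Transportation = "taxi",
    Transportation = "ferry_terminal",
    Financial = "atm", Financial = "bank", Financial = "bureau_de_change",
    Healthcare = "clinic", Healthcare = "dentist", Healthcare = "doctors",
    Healthcare = "hospital", Healthcare = "pharmacy",
    Healthcare = "veterinary", Healthcare = "nursing_home",
    Entertainment = "cinema", Entertainment = "theatre",
    Entertainment = "nightclub", Entertainment = "casino",
    Entertainment = "community_centre", Entertainment = "events_venue",
    `Arts & Culture` = "arts_centre", `Arts & Culture` = "gallery",
    `Arts & Culture` = "museum", `Arts & Culture` = "studio",
    `Arts & Culture` = "music_venue",
    Others = "place_of_worship", Others = "police", Others = "fire_station",
    Others = "post_office", Others = "townhall", Others = "marketplace",
    Others = "recycling", Others = "shelter", Others = "drinking_water",
    Others = "bench")
  keys
}

#' Distance-band grid
#'
#' Ascending list of cumulative distance thresholds (metres). With the
#' defaults (200 m to 2,000 m in 200 m steps) the grid has 10 bands, so a
#' 53-key configuration yields 530 POI features.
#'
#' @param d_min,d_max smallest and largest band distance, metres.
#' @param step band increment, metres; `(d_max - d_min)` must be divisible
#'   by `step`.
#' @return numeric vector of band distances
#' @examples
#' band_grid()                 # 200, 400, ..., 2000
#' band_grid(500, 500, 100)    # a single band
#' @export
band_grid <- function(d_min = 200, d_max = 2000, step = 200) {
  assert_scalar_number(d_min, "d_min")
  assert_scalar_number(d_max, "d_max")
  assert_scalar_number(step, "step")
  if (d_min <= 0 || d_min > d_max || step <= 0)
    stopf("need 0 < d_min <= d_max and step > 0")
  k <- (d_max - d_min) / step
  if (abs(k - round(k)) > 1e-9)
    stopf("(d_max - d_min) = %g is not divisible by step = %g", d_max - d_min, step)
  seq(d_min, d_max, by = step)
}

#' Binary POI distance-band features
#'
#' For every node, key and band distance d, the indicator is 1 iff at least
#' one POI of that key lies within d metres (straight-line haversine) of the
#' node. Bands are cumulative ("within d"), so for a fixed node and key the
#' indicators are non-decreasing across ascending bands; `annular = TRUE`
#' switches to disjoint ring semantics instead.
#'
#' @param net a `road_network`
#' @param pois data.frame with columns `poi_id`, `key`, `lat`, `lon`.
#' @param keys character vector of POI keys defining the columns; defaults
#'   to the 53-key list in [poi_keys()].
#' @param bands ascending band distances in metres; see [band_grid()].
#' @param annular use disjoint rings instead of cumulative bands.
#' @param strict error (rather than drop with a warning) on POIs whose key
#'   is not in `keys`.
#' @return binary matrix (nodes x keys*bands), columns ordered key-major
#'   then band-ascending, named `<key>@<band>m`; rownames = node ids
#' @export
extract_poi_features <- function(net, pois, keys = poi_keys(),
                                 bands = band_grid(), annular = FALSE,
                                 strict = FALSE) {
  stopifnot(inherits(net, "road_network"))
  keys <- unname(keys)
  if (!length(keys)) stopf("`keys` must be non-empty")
  if (is.unsorted(bands, strictly = TRUE)) stopf("`bands` must be strictly ascending")
  need <- c("key", "lat", "lon")
  if (nrow(pois) && !all(need %in% names(pois)))
    stopf("`pois` must have columns %s", paste(need, collapse = ", "))

  if (nrow(pois)) {
    unknown <- !(pois$key %in% keys)
    if (any(unknown)) {
      if (strict) stopf("%d POIs carry keys outside the configured key list", sum(unknown))
      warnf("dropping %d POIs with unknown keys", sum(unknown))
      pois <- pois[!unknown, , drop = FALSE]
    }
  }

  nn <- nrow(net$nodes)
  cols <- as.vector(t(outer(keys, bands, function(k, b) sprintf("%s@%gm", k, b))))
  out <- matrix(0L, nrow = nn, ncol = length(keys) * length(bands),
                dimnames = list(net$nodes$node_id, cols))
  if (nrow(pois)) {
    for (ki in seq_along(keys)) {
      sel <- pois$key == keys[ki]
      if (!any(sel)) next
      # min distance from every node to the POIs of this key
      dmin <- rep(Inf, nn)
      plat <- pois$lat[sel]; plon <- pois$lon[sel]
      for (j in seq_along(plat)) {
        dj <- haversine_distance(net$nodes$lat, net$nodes$lon, plat[j], plon[j])
        dmin <- pmin(dmin, dj)
      }
      ind <- outer(dmin, bands, "<=") * 1L
      if (annular && length(bands) > 1L) {
        ind[, -1L] <- ind[, -1L, drop = FALSE] - ind[, -ncol(ind), drop = FALSE]
      }
      out[, (ki - 1L) * length(bands) + seq_along(bands)] <- ind
    }
  }
  out
}

#' Read POIs from CSV
#' @param file CSV with header `poi_id,key,lat,lon`
#' @return data.frame of POIs
#' @export
read_pois_csv <- function(file) {
  pois <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("poi_id", "key", "lat", "lon")
  if (!all(need %in% names(pois)))
    stopf("POI CSV '%s' must have columns %s", file, paste(need, collapse = ", "))
  pois
}

#' Read POIs from GeoJSON points
#'
#' Expects a FeatureCollection of Point features with a `key` property
#' (optionally `poi_id`).
#'
#' @param file path to a GeoJSON document
#' @return data.frame with columns `poi_id,key,lat,lon`
#' @export
read_pois_geojson <- function(file) {
  gj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) stopf("'%s' is not a GeoJSON FeatureCollection", file)
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Point"))
      stopf("feature %d is not a Point", i)
    co <- unlist(f$geometry$coordinates)
    data.frame(poi_id = as.character(f$properties$poi_id %||% i),
               key = as.character(f$properties$key),
               lat = co[2], lon = co[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a feature matrix (POI, centrality or embedding block) as CSV
#' @param mat matrix with node-id rownames
#' @param file output path
#' @return `file`, invisibly
#' @export
write_features_csv <- function(mat, file) {
  df <- data.frame(node_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
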