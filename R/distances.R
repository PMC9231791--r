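#' Great-circle distance between road points
#'
#' Haversine distance on a sphere of radius 6,371,000 m (WGS84 mean radius).
#' Vectorised over both arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in metres
#' @examples
#' haversine_distance(0, 0, 0, 1)  # ~111,195 m: one degree along the equator
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stopf("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

#' All-pairs node distance matrix
#'
#' Symmetric matrix of great-circle distances (metres) between every pair of
#' road nodes; zero on the diagonal. The computation is O(n^2) in time and
#' memory, so a node cap guards against accidental use on very large
#' networks.
#'
#' @param net a `road_network`
#' @param max_nodes refuse networks larger than this (default 20000).
#' @return numeric matrix with node ids as dimnames, class `dist_matrix`
#' @export
distance_matrix <- function(net, max_nodes = 20000L) {
  stopifnot(inherits(net, "road_network"))
  n <- nrow(net$nodes)
  if (n > max_nodes)
    stopf("network has %d nodes, above the max_nodes cap of %d; raise the cap explicitly if intended",
          n, max_nodes)
  p <- cbind(net$nodes$lon, net$nodes$lat)
  rad <- p * pi / 180
  sin_lat <- sin(rad[, 2]); cos_lat <- cos(rad[, 2])
  # haversine expanded with outer products: fast O(n^2) without per-pair calls
  dlat <- outer(rad[, 2], rad[, 2], "-") / 2
  dlon <- outer(rad[, 1], rad[, 1], "-") / 2
  a <- sin(dlat)^2 + (cos_lat %o% cos_lat) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  d <- 2 * 6371000 * asin(sqrt(a))
  diag(d) <- 0
  dimnames(d) <- list(net$nodes$node_id, net$nodes$node_id)
  class(d) <- c("dist_matrix", class(d))
  d
}
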