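#' Construct a road network
#'
#' A road network is an undirected, unweighted, connected graph whose nodes
#' are geolocated road points (WGS84). Self-loops and duplicate edges are
#' rejected; if the input is disconnected the largest connected component is
#' retained with a warning (set `require_connected = TRUE` to error instead).
#'
#' @param nodes data.frame with columns `node_id`, `lat`, `lon`. Ids are
#'   treated as opaque strings and must be unique; `lat` in \[-90, 90\],
#'   `lon` in \[-180, 180\].
#' @param edges data.frame with columns `u`, `v` naming node ids.
#' @param require_connected error (rather than subset) on disconnected input.
#' @return An object of class `road_network`: a list with `nodes` (data.frame
#'   `node_id,lat,lon`) and `edges` (data.frame `u,v`).
#' @examples
#' nodes <- data.frame(node_id = c("a", "b", "c"),
#'                     lat = c(47.5, 47.501, 47.502),
#'                     lon = c(-52.7, -52.7, -52.7))
#' edges <- data.frame(u = c("a", "b"), v = c("b", "c"))
#' net <- road_network(nodes, edges)
#' @export
road_network <- function(nodes, edges, require_connected = FALSE) {
  need <- c("node_id", "lat", "lon")
  if (!all(need %in% names(nodes)))
    stopf("`nodes` must have columns %s", paste(need, collapse = ", "))
  if (!all(c("u", "v") %in% names(edges)))
    stopf("`edges` must have columns u, v")
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      lat = as.numeric(nodes$lat),
                      lon = as.numeric(nodes$lon),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id))
    stopf("duplicate node ids: %s",
          paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  if (any(!is.finite(nodes$lat)) || any(abs(nodes$lat) > 90))
    stopf("latitudes must lie in [-90, 90]")
  if (any(!is.finite(nodes$lon)) || any(abs(nodes$lon) > 180))
    stopf("longitudes must lie in [-180, 180]")
  if (nrow(nodes) < 2L) stopf("a road network needs at least 2 nodes")

  edges <- data.frame(u = as.character(edges$u), v = as.character(edges$v),
                      stringsAsFactors = FALSE)
  missing <- setdiff(c(edges$u, edges$v), nodes$node_id)
  if (length(missing))
    stopf("edge endpoints not in node table: %s",
          paste(head(missing, 5L), collapse = ", "))
  if (any(edges$u == edges$v)) stopf("self-loops are not allowed")
  key <- ifelse(edges$u < edges$v, paste(edges$u, edges$v), paste(edges$v, edges$u))
  if (anyDuplicated(key)) {
    edges <- edges[!duplicated(key), , drop = FALSE]
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$node_id)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    if (require_connected) stopf("network is disconnected (%d components)", comp$no)
    keep_comp <- which.max(comp$csize)
    keep <- names(comp$membership)[comp$membership == keep_comp]
    warnf("input graph is disconnected; keeping largest component (%d of %d nodes)",
          length(keep), nrow(nodes))
    nodes <- nodes[nodes$node_id %in% keep, , drop = FALSE]
    edges <- edges[edges$u %in% keep & edges$v %in% keep, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes in a road network
#' @param net a `road_network`
#' @return integer node count
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' Convert a road network to an igraph object
#'
#' The graph is undirected and unweighted; vertex names are node ids and
#' vertex order follows the node table.
#'
#' @param net a `road_network`
#' @return an `igraph` graph
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "road_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes$node_id)
}

#' Read a road network from node/edge CSV files
#'
#' @param node_file CSV with header `node_id,lat,lon`.
#' @param edge_file CSV with header `u,v`.
#' @param ... passed to [road_network()].
#' @return a `road_network`
#' @export
read_network_csv <- function(node_file, edge_file, ...) {
  nodes <- tryCatch(read.csv(node_file, stringsAsFactors = FALSE),
                    error = function(e) stopf("cannot parse node CSV '%s': %s",
                                              node_file, conditionMessage(e)))
  edges <- tryCatch(read.csv(edge_file, stringsAsFactors = FALSE),
                    error = function(e) stopf("cannot parse edge CSV '%s': %s",
                                              edge_file, conditionMessage(e)))
  road_network(nodes, edges, ...)
}

#' Default OSM highway whitelist
#'
#' Highway tag values regarded as walkable or drivable roads. Ways whose
#' `highway` tag is not in this list (including ways with no highway tag at
#' all, e.g. waterways or building outlines) are dropped when reading OSM
#' XML. `*_link` variants of the major classes are included.
#'
#' @return character vector of highway tag values
#' @export
highway_whitelist <- function() {
  base <- c("motorway", "trunk", "primary", "secondary", "tertiary",
            "unclassified", "residential", "service", "footway", "path",
            "pedestrian", "living_street", "track")
  links <- paste0(c("motorway", "trunk", "primary", "secondary", "tertiary"),
                  "_link")
  c(base, links)
}

#' Read a road network from OSM XML
#'
#' Parses `<node>` and `<way>` elements; only ways carrying a `highway` tag
#' whose value is in `whitelist` are kept, and consecutive node references
#' within a kept way become edges. Nodes not referenced by any kept way are
#' dropped.
#'
#' @param file path to an OSM XML document.
#' @param whitelist highway tag values to keep; see [highway_whitelist()].
#' @param ... passed to [road_network()].
#' @return a `road_network`
#' @export
read_network_osm <- function(file, whitelist = highway_whitelist(), ...) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) stopf("cannot parse OSM XML '%s': %s",
                                            file, conditionMessage(e)))
  node_els <- xml2::xml_find_all(doc, ".//node")
  ids <- xml2::xml_attr(node_els, "id")
  lat <- as.numeric(xml2::xml_attr(node_els, "lat"))
  lon <- as.numeric(xml2::xml_attr(node_els, "lon"))
  ways <- xml2::xml_find_all(doc, ".//way")
  eu <- character(0); ev <- character(0)
  for (w in ways) {
    tags <- xml2::xml_find_all(w, "./tag")
    k <- xml2::xml_attr(tags, "k"); v <- xml2::xml_attr(tags, "v")
    hw <- v[k == "highway"]
    if (!length(hw) || !hw[1] %in% whitelist) next
    refs <- xml2::xml_attr(xml2::xml_find_all(w, "./nd"), "ref")
    if (length(refs) >= 2L) {
      eu <- c(eu, refs[-length(refs)])
      ev <- c(ev, refs[-1L])
    }
  }
  if (!length(eu)) stopf("no highway-tagged ways matched the whitelist; empty graph")
  used <- unique(c(eu, ev))
  keep <- ids %in% used
  road_network(data.frame(node_id = ids[keep], lat = lat[keep], lon = lon[keep],
                          stringsAsFactors = FALSE),
               data.frame(u = eu, v = ev, stringsAsFactors = FALSE), ...)
}

#' Write a node table with centrality columns
#'
#' @param net a `road_network`
#' @param centr a `CentralityTable` as returned by [compute_centralities()]
#' @param file output CSV path
#' @return `file`, invisibly
#' @export
write_centralities_csv <- function(net, centr, file) {
  stopifnot(identical(rownames(centr), net$nodes$node_id))
  out <- cbind(net$nodes, as.data.frame(centr))
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}
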