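#' Generate a synthetic road network
#'
#' Builds a connected geolocated road graph for simulation studies: either a
#' jittered square `grid` lattice (4-neighbour streets, the default) or a
#' `random_geometric` graph (uniform points connected within a radius tuned
#' to reach connectivity at a road-like mean degree). Coordinates are WGS84
#' degrees around a configurable centre with roughly `spacing_m` metres
#' between neighbouring nodes.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param kind `"grid"` or `"random_geometric"`.
#' @param seed integer seed; the same seed reproduces the identical network.
#' @param center named vector `c(lat=, lon=)` of the city centre.
#' @param spacing_m target neighbour spacing in metres.
#' @return a `road_network`
#' @export
make_network <- function(n_nodes, kind = c("grid", "random_geometric"),
                         seed = 1L, center = c(lat = 47.5, lon = -52.7),
                         spacing_m = 100) {
  kind <- match.arg(kind)
  if (n_nodes < 2L) stopf("n_nodes must be >= 2")
  set.seed(as.integer(seed))
  lat0 <- center[["lat"]]; lon0 <- center[["lon"]]
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(lat0 * pi / 180)
  ids <- sprintf("n%04d", seq_len(n_nodes))

  if (kind == "grid") {
    nr <- floor(sqrt(n_nodes))
    nc <- ceiling(n_nodes / nr)
    cell <- seq_len(n_nodes) - 1L
    row <- cell %/% nc
    col <- cell %% nc
    jit_x <- runif(n_nodes, -0.2, 0.2)
    jit_y <- runif(n_nodes, -0.2, 0.2)
    x <- (col + jit_x) * spacing_m
    y <- (row + jit_y) * spacing_m
    idx <- function(r, c) r * nc + c + 1L
    eu <- integer(0); ev <- integer(0)
    for (i in seq_len(n_nodes)) {
      r <- row[i]; c <- col[i]
      if (c + 1L < nc && idx(r, c + 1L) <= n_nodes) {
        eu <- c(eu, i); ev <- c(ev, idx(r, c + 1L))
      }
      if (idx(r + 1L, c) <= n_nodes) {
        eu <- c(eu, i); ev <- c(ev, idx(r + 1L, c))
      }
    }
    nodes <- data.frame(node_id = ids,
                        lat = lat0 + y / m_per_deg_lat,
                        lon = lon0 + x / m_per_deg_lon,
                        stringsAsFactors = FALSE)
    edges <- data.frame(u = ids[eu], v = ids[ev], stringsAsFactors = FALSE)
    return(road_network(nodes, edges, require_connected = TRUE))
  }

  # random geometric: radius targeting a road-like mean degree (~5);
  # residual components are stitched with a bridge edge between their
  # geometrically nearest node pair, keeping the degree distribution intact
  side <- sqrt(n_nodes) * spacing_m
  target_deg <- 5
  r <- sqrt(target_deg * side^2 / (pi * n_nodes))
  x <- runif(n_nodes, 0, side)
  y <- runif(n_nodes, 0, side)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  adj <- d2 <= r^2
  diag(adj) <- FALSE
  ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  if (nrow(ij)) g <- igraph::add_edges(g, t(ij))
  for (attempt in seq_len(n_nodes)) {
    comp <- igraph::components(g)
    if (comp$no == 1L) break
    main <- which(comp$membership == which.max(comp$csize))
    rest <- which(comp$membership != which.max(comp$csize))
    sub <- d2[rest, main, drop = FALSE]
    best <- arrayInd(which.min(sub), dim(sub))
    bridge <- c(rest[best[1]], main[best[2]])
    g <- igraph::add_edges(g, bridge)
    ij <- rbind(ij, bridge)
  }
  if (igraph::components(g)$no != 1L)
    stopf("could not generate a connected random geometric graph")
  nodes <- data.frame(node_id = ids,
                      lat = lat0 + y / m_per_deg_lat,
                      lon = lon0 + x / m_per_deg_lon,
                      stringsAsFactors = FALSE)
  edges <- data.frame(u = ids[ij[, 1]], v = ids[ij[, 2]],
                      stringsAsFactors = FALSE)
  road_network(nodes, edges, require_connected = TRUE)
}

#' Generate synthetic POIs
#'
#' Places categorized POIs near the road network: a `clustering` fraction
#' concentrates around a "downtown" subset of nodes (emulating the amenity
#' density gradient of real cities), the rest scatter near random nodes.
#' Keys are drawn from `keys` with the given weights.
#'
#' @param net a `road_network`
#' @param n_pois number of POIs.
#' @param keys candidate POI keys; defaults to [poi_keys()].
#' @param seed integer seed.
#' @param clustering probability a POI lands downtown, in \[0, 1\].
#' @param downtown_frac fraction of nodes (nearest to a random downtown
#'   centre node) that constitute downtown.
#' @param key_weights sampling weights over `keys` (default uniform).
#' @param offset_m POI scatter around its host node, metres (sd).
#' @return data.frame with columns `poi_id`, `key`, `lat`, `lon`; attribute
#'   `downtown_ids` records the downtown node ids
#' @export
make_pois <- function(net, n_pois, keys = poi_keys(), seed = 1L,
                      clustering = 0.7, downtown_frac = 0.2,
                      key_weights = NULL, offset_m = 60) {
  if (!length(keys)) stopf("`keys` must be non-empty")
  keys <- unname(keys)
  set.seed(as.integer(seed))
  nn <- nrow(net$nodes)
  empty <- data.frame(poi_id = character(0), key = character(0),
                      lat = numeric(0), lon = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_pois == 0L) return(empty)
  centre_node <- sample.int(nn, 1L)
  d_centre <- haversine_distance(net$nodes$lat, net$nodes$lon,
                                 net$nodes$lat[centre_node],
                                 net$nodes$lon[centre_node])
  k_down <- max(1L, round(downtown_frac * nn))
  downtown <- order(d_centre)[seq_len(k_down)]
  host <- ifelse(runif(n_pois) < clustering,
                 sample(downtown, n_pois, replace = TRUE),
                 sample.int(nn, n_pois, replace = TRUE))
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(net$nodes$lat[1] * pi / 180)
  out <- data.frame(
    poi_id = sprintf("p%04d", seq_len(n_pois)),
    key = sample(keys, n_pois, replace = TRUE, prob = key_weights),
    lat = net$nodes$lat[host] + rnorm(n_pois, 0, offset_m) / m_per_deg_lat,
    lon = net$nodes$lon[host] + rnorm(n_pois, 0, offset_m) / m_per_deg_lon,
    stringsAsFactors = FALSE)
  attr(out, "downtown_ids") <- net$nodes$node_id[downtown]
  out
}

#' Latent walkability field
#'
#' The synthetic ground truth: a per-node score in \[0, 100\] combining
#' (1) proximity to the nearest POI (closer = more walkable), (2) closeness
#' centrality in the road graph, and (3) a seeded smooth spatial field (a
#' sum of random low-frequency cosine waves), each min-max normalized to
#' \[0, 1\] before the weighted sum, which is then min-max scaled to
#' \[0, 100\].
#'
#' @param net a `road_network`
#' @param pois POI data.frame (may have zero rows; the POI term is then 0).
#' @param weights named non-negative weights `c(poi=, closeness=, field=)`,
#'   not all zero.
#' @param seed integer seed (drives only the spatial field).
#' @param field_waves number of cosine components in the spatial field.
#' @return numeric vector of scores in \[0, 100\] named by node id
#' @export
latent_walkability <- function(net, pois,
                               weights = c(poi = 1, closeness = 1, field = 1),
                               seed = 1L, field_waves = 4L) {
  w <- c(poi = 0, closeness = 0, field = 0)
  w[names(weights)] <- weights
  if (any(w < 0) || sum(w) == 0) stopf("weights must be non-negative, not all zero")
  set.seed(as.integer(seed))
  nn <- nrow(net$nodes)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / (r[2] - r[1])
  }

  poi_term <- rep(0, nn)
  if (w[["poi"]] > 0 && nrow(pois)) {
    dmin <- rep(Inf, nn)
    for (j in seq_len(nrow(pois))) {
      dj <- haversine_distance(net$nodes$lat, net$nodes$lon,
                               pois$lat[j], pois$lon[j])
      dmin <- pmin(dmin, dj)
    }
    poi_term <- norm01(-dmin)
  }

  clos_term <- rep(0, nn)
  if (w[["closeness"]] > 0) {
    clos_term <- norm01(as.numeric(igraph::closeness(as_igraph(net),
                                                     normalized = TRUE)))
  }

  field_term <- rep(0, nn)
  if (w[["field"]] > 0) {
    x <- norm01(net$nodes$lon); y <- norm01(net$nodes$lat)
    f <- rep(0, nn)
    for (k in seq_len(field_waves)) {
      fx <- runif(1, 0.5, 2.5); fy <- runif(1, 0.5, 2.5)
      ph <- runif(2, 0, 2 * pi)
      f <- f + cos(2 * pi * fx * x + ph[1]) * cos(2 * pi * fy * y + ph[2])
    }
    field_term <- norm01(f)
  }

  score <- w[["poi"]] * poi_term + w[["closeness"]] * clos_term +
    w[["field"]] * field_term
  out <- 100 * norm01(score)
  names(out) <- net$nodes$node_id
  out
}

#' Generate crowd-style ranked submissions
#'
#' Samples `n_subs` submissions of `group_size` distinct nodes each. After
#' the first submission, every slot is re-drawn from previously used nodes
#' with probability `overlap_rate` (creating natural anchors at roughly
#' that repeated-slot rate, capped at `max_reuse` rankings per location);
#' the remaining slots draw fresh nodes. Each submission perceives
#' `latent + Normal(0, noise_sigma)` per node and orders its nodes by
#' ascending perceived score, so with `noise_sigma = 0` every submission is
#' exactly consistent with the latent order.
#'
#' @param net a `road_network`
#' @param latent named latent score vector from [latent_walkability()].
#' @param n_subs number of submissions (default 210).
#' @param group_size locations per submission (default 5).
#' @param overlap_rate probability a slot reuses an already-used node
#'   (default 0.19, matching a repeated-slot share of roughly 19%).
#' @param noise_sigma per-submission opinion noise sd on the 0-100 scale.
#' @param seed integer seed.
#' @param max_reuse maximum number of submissions a single location may
#'   appear in (default 3).
#' @param n_users number of distinct user ids to spread submissions over.
#' @return a `submission_set`
#' @export
make_submissions <- function(net, latent, n_subs = 210L, group_size = 5L,
                             overlap_rate = 0.19, noise_sigma = 0,
                             seed = 1L, max_reuse = 3L, n_users = 35L) {
  nn <- nrow(net$nodes)
  if (nn < group_size) stopf("network too small for group_size = %d", group_size)
  ids <- net$nodes$node_id
  fresh_need <- n_subs * group_size * (1 - overlap_rate)
  if (fresh_need > nn * 1.15)
    stopf("overlap_rate %.2f is infeasible: ~%.0f fresh slots needed but only %d nodes",
          overlap_rate, fresh_need, nn)
  set.seed(as.integer(seed))
  use_count <- setNames(integer(nn), ids)
  subs <- vector("list", n_subs)
  for (j in seq_len(n_subs)) {
    chosen <- character(0)
    for (s in seq_len(group_size)) {
      reuse_pool <- ids[use_count > 0L & use_count < max_reuse &
                          !(ids %in% chosen)]
      fresh_pool <- ids[use_count == 0L & !(ids %in% chosen)]
      pick <- NULL
      if (j > 1L && length(reuse_pool) && runif(1) < overlap_rate) {
        pick <- sample(reuse_pool, 1L)
      } else if (length(fresh_pool)) {
        pick <- sample(fresh_pool, 1L)
      } else if (length(reuse_pool)) {
        pick <- sample(reuse_pool, 1L)
      } else {
        stopf("exhausted node pool at submission %d (max_reuse too tight)", j)
      }
      chosen <- c(chosen, pick)
    }
    perceived <- latent[chosen] + rnorm(group_size, 0, noise_sigma)
    subs[[j]] <- chosen[order(perceived, chosen)]
    use_count[chosen] <- use_count[chosen] + 1L
  }
  users <- sprintf("u%03d", sample(rep_len(seq_len(n_users), n_subs)))
  submission_set(subs, users, group_size = group_size)
}

#' Hand-built verification submission sets
#'
#' Three tiny artificial scenarios for validating the aggregation rules,
#' each a `submission_set` plus node coordinates (a `coords` attribute):
#'
#' * `loop`: two submissions sharing two anchors whose orders cross,
#'   forming a loop (a genuine conflict); 8 unique nodes.
#' * `multi_anchor`: three submissions tied together by four anchor nodes.
#' * `extremes`: two submissions `1..5` and `1,6,7,8,5` sharing their first
#'   and last nodes, so node 1 must rank lowest and node 5 highest in every
#'   valid linear extension (there are exactly choose(6,3) = 20 of them).
#'
#' @return named list of `submission_set` objects
#' @export
verification_fixtures <- function() {
  coords_for <- function(ids) {
    k <- length(ids)
    data.frame(node_id = ids,
               lat = 47.5 + (seq_len(k) - 1) * 0.001,
               lon = -52.7 + rep(c(0, 0.001), length.out = k),
               stringsAsFactors = FALSE)
  }
  fix <- list(
    loop = submission_set(list(c("1", "2", "3", "4", "5"),
                               c("4", "6", "7", "2", "8"))),
    multi_anchor = submission_set(list(c("1", "2", "3", "4", "5"),
                                       c("2", "6", "7", "3", "8"),
                                       c("9", "4", "10", "5", "11"))),
    extremes = submission_set(list(c("1", "2", "3", "4", "5"),
                                   c("1", "6", "7", "8", "5"))))
  for (nm in names(fix)) {
    attr(fix[[nm]], "coords") <- coords_for(submitted_nodes(fix[[nm]]))
  }
  fix
}
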