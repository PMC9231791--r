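#' Eight road-network centrality features
#'
#' Computes, for every node of a connected, undirected, unweighted road
#' network, the eight structural features used as the "network" feature
#' block: betweenness centrality, closeness centrality, clustering
#' coefficient, degree, eccentricity, neighborhood connectivity, stress
#' centrality and topological coefficient. All shortest-path quantities use
#' hop distance (the graph is unweighted).
#'
#' Definitions (NetworkAnalyzer-style):
#' * betweenness: sum over pairs of sigma_st(v)/sigma_st, normalized by
#'   2/((n-1)(n-2)) so values lie in \[0,1\];
#' * closeness: (n-1) / sum of hop distances to all other nodes;
#' * clustering coefficient: 2T(v)/(k(k-1)) with T(v) the triangles at v;
#'   0 when degree < 2;
#' * degree: neighbour count;
#' * eccentricity: maximum hop distance to any node;
#' * neighborhood connectivity: mean degree of the node's neighbours;
#' * stress: raw count of all-pairs shortest paths passing through the node
#'   as an interior vertex;
#' * topological coefficient: mean over nodes m sharing at least one
#'   neighbour with v of J(v,m)/k(v), where J(v,m) is the shared-neighbour
#'   count plus 1 if v and m are adjacent; 0 when degree < 2.
#'
#' @param net a connected `road_network`
#' @return numeric matrix (nodes x 8), rownames = node ids, class
#'   `centrality_table`
#' @export
compute_centralities <- function(net) {
  g <- as_igraph(net)
  if (igraph::components(g)$no > 1L)
    stopf("centralities require a connected network (eccentricity/closeness undefined otherwise)")
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)

  betw <- if (n > 2) igraph::betweenness(g, normalized = TRUE) else rep(0, n)
  clos <- igraph::closeness(g, normalized = TRUE)
  clus <- igraph::transitivity(g, type = "local", isolates = "zero")
  clus[deg < 2] <- 0
  ecc <- igraph::eccentricity(g)
  nc <- igraph::knn(g)$knn          # mean neighbour degree
  nc[is.nan(nc)] <- 0
  stress <- stress_centrality(g)
  topo <- topological_coefficient(g)

  out <- cbind(betweenness = as.numeric(betw),
               closeness = as.numeric(clos),
               clustering_coefficient = as.numeric(clus),
               degree = as.numeric(deg),
               eccentricity = as.numeric(ecc),
               neighborhood_connectivity = as.numeric(nc),
               stress = as.numeric(stress),
               topological_coefficient = as.numeric(topo))
  rownames(out) <- igraph::V(g)$name
  out <- out[net$nodes$node_id, , drop = FALSE]
  class(out) <- c("centrality_table", class(out))
  out
}

#' Stress centrality
#'
#' Raw number of all-pairs shortest paths that pass through each node as an
#' interior vertex, counted once per unordered endpoint pair. Uses a
#' Brandes-style breadth-first accumulation (O(nm) on unweighted graphs).
#'
#' @param g an undirected `igraph` graph
#' @return numeric vector named by vertex
#' @export
stress_centrality <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  total <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_seen <- integer(0)
    preds <- vector("list", n)
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        order_seen <- c(order_seen, v)
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_seen)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] * (1 + delta[w] / sigma[w])
      }
      if (w != s) total[w] <- total[w] + delta[w]
    }
  }
  out <- total / 2   # each unordered pair visited from both endpoints
  names(out) <- igraph::V(g)$name
  out
}

#' Topological coefficient
#'
#' For each node v with degree >= 2: the mean of J(v,m)/k(v) over all nodes
#' m != v that share at least one neighbour with v, where J(v,m) is the
#' number of shared neighbours plus 1 if v and m are adjacent. Nodes of
#' degree < 2 get 0.
#'
#' @param g an undirected `igraph` graph
#' @return numeric vector named by vertex
#' @export
topological_coefficient <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  deg <- rowSums(A)
  shared <- A %*% A           # shared-neighbour counts
  J <- shared + A             # +1 when adjacent
  out <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    partners <- which(shared[v, ] > 0)
    partners <- setdiff(partners, v)
    if (!length(partners)) next
    out[v] <- mean(J[v, partners]) / deg[v]
  }
  names(out) <- igraph::V(g)$name
  out
}
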