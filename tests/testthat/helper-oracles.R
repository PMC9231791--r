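# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles are written from first principles (plain loops over definitions)
# and never call the implementation paths they check.

# small road_network from an edge list; coordinates laid out on a grid so
# all geometry is valid but incidental
toy_net <- function(edges, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(edges$u, edges$v)))
  k <- length(ids)
  nodes <- data.frame(node_id = ids,
                      lat = 47.5 + ((seq_len(k) - 1) %% 7) * 0.001,
                      lon = -52.7 + ((seq_len(k) - 1) %/% 7) * 0.001,
                      stringsAsFactors = FALSE)
  road_network(nodes, edges)
}

path_net <- function(n, ids = sprintf("p%02d", seq_len(n))) {
  toy_net(data.frame(u = ids[-n], v = ids[-1], stringsAsFactors = FALSE), ids)
}

star_net <- function(leaves = 3L) {
  ids <- c("c", sprintf("l%d", seq_len(leaves)))
  toy_net(data.frame(u = rep("c", leaves), v = ids[-1],
                     stringsAsFactors = FALSE), ids)
}

# all permutations of a vector (insertion construction)
all_perms <- function(v) {
  out <- list(v[1])
  for (k in seq_along(v)[-1]) {
    nxt <- vector("list", length(out) * k)
    i <- 0L
    for (p in out) {
      for (pos in 0:(k - 1L)) {
        i <- i + 1L
        nxt[[i]] <- append(p, v[k], after = pos)
      }
    }
    out <- nxt
  }
  out
}

is_subsequence <- function(sub, ord) {
  pos <- match(sub, ord)
  !anyNA(pos) && all(diff(pos) > 0)
}

# brute-force set of linear extensions of a submission set over its nodes
valid_extensions <- function(subs) {
  Filter(function(p) all(vapply(subs$nodes, is_subsequence, logical(1),
                                ord = p)),
         all_perms(submitted_nodes(subs)))
}

# --- loss / consistency oracles (explicit loops over definitions) ---------

oracle_submission_loss <- function(sub, order_vec) {
  pos <- match(sub, order_vec)
  o_w <- integer(length(sub))
  for (i in seq_along(sub)) o_w[i] <- sum(pos <= pos[i])  # induced rank
  s <- 0
  for (i in seq_along(sub)) s <- s + abs(i - o_w[i])
  s
}

oracle_preserved_pairs <- function(sub, order_vec) {
  pos <- match(sub, order_vec)
  kept <- 0L; tot <- 0L
  for (i in seq_along(sub)) for (j in seq_along(sub)) {
    if (i < j) {
      tot <- tot + 1L
      if (pos[i] < pos[j]) kept <- kept + 1L
    }
  }
  c(kept = kept, total = tot)
}

oracle_kendall <- function(sub, order_vec) {
  pos <- match(sub, order_vec)
  conc <- 0L; disc <- 0L
  for (i in seq_along(sub)) for (j in seq_along(sub)) {
    if (i < j) {
      if (pos[i] < pos[j]) conc <- conc + 1L else disc <- disc + 1L
    }
  }
  (conc - disc) / choose(length(sub), 2)
}

# --- centrality oracle: all 8 measures from scratch on a tiny graph -------
# adjacency matrix in; all-pairs hop distances and shortest-path counts by
# dynamic programming over distance levels

oracle_centralities <- function(A) {
  n <- nrow(A)
  # BFS distances via repeated neighbour expansion
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in 1:n) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ] == 1))
        if (D[s, w] > d) { D[s, w] <- d; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
  }
  # shortest-path counts
  N <- matrix(0, n, n); diag(N) <- 1
  for (s in 1:n) {
    for (d in 1:max(D[s, D[s, ] < Inf])) {
      for (t in which(D[s, ] == d)) {
        for (u in which(A[t, ] == 1)) {
          if (D[s, u] == d - 1) N[s, t] <- N[s, t] + N[s, u]
        }
      }
    }
  }
  deg <- rowSums(A)
  betw <- numeric(n); stress <- numeric(n)
  for (v in 1:n) for (s in 1:n) for (t in 1:n) {
    if (s < t && s != v && t != v && D[s, v] + D[v, t] == D[s, t]) {
      paths_through <- N[s, v] * N[v, t]
      stress[v] <- stress[v] + paths_through
      betw[v] <- betw[v] + paths_through / N[s, t]
    }
  }
  if (n > 2) betw <- betw * 2 / ((n - 1) * (n - 2))
  clos <- (n - 1) / rowSums(D)
  clus <- numeric(n)
  for (v in 1:n) {
    nb <- which(A[v, ] == 1); k <- length(nb)
    if (k >= 2) {
      tri <- 0
      for (a in nb) for (b in nb) if (a < b && A[a, b] == 1) tri <- tri + 1
      clus[v] <- 2 * tri / (k * (k - 1))
    }
  }
  ecc <- apply(D, 1, max)
  nc <- numeric(n)
  for (v in 1:n) {
    nb <- which(A[v, ] == 1)
    if (length(nb)) nc[v] <- mean(deg[nb])
  }
  topo <- numeric(n)
  for (v in 1:n) {
    if (deg[v] < 2) next
    js <- numeric(0)
    for (m in 1:n) {
      if (m == v) next
      shared <- sum(A[v, ] == 1 & A[m, ] == 1)
      if (shared > 0) js <- c(js, shared + (A[v, m] == 1))
    }
    if (length(js)) topo[v] <- mean(js) / deg[v]
  }
  cbind(betweenness = betw, closeness = clos, clustering_coefficient = clus,
        degree = deg, eccentricity = ecc, neighborhood_connectivity = nc,
        stress = stress, topological_coefficient = topo)
}

# random connected graph with <= n nodes (adjacency + road_network)
random_connected_graph <- function(n, p_edge = 0.35, seed = 1L) {
  set.seed(seed)
  repeat {
    A <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < p_edge) A[i, j] <- A[j, i] <- 1L
    # connectivity via reachability
    reach <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(which(rowSums(A[, frontier, drop = FALSE]) > 0), reach)
      reach <- c(reach, nxt); frontier <- nxt
    }
    if (length(reach) == n) break
  }
  ids <- sprintf("g%02d", 1:n)
  ij <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  list(A = A,
       net = toy_net(data.frame(u = ids[ij[, 1]], v = ids[ij[, 2]],
                                stringsAsFactors = FALSE), ids),
       ids = ids)
}

# --- study-scale simulation cache (shared by the acceptance checks) -------
# one noiseless, study-shaped synthetic collection per master seed:
# 1,000-node grid city, 400 POIs, 210 submissions of 5 with ~19% repeated
# slots, GLEPO with 30 iterations and virtual links on
.study_cache <- new.env(parent = emptyenv())

study_run <- function(master_seed, noise_sigma = 0) {
  key <- paste0("s", master_seed, "_n", noise_sigma)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  net <- make_network(1000, "grid", seed = derive_study_seed(master_seed, 1))
  pois <- make_pois(net, 400, seed = derive_study_seed(master_seed, 2))
  lat <- latent_walkability(net, pois, seed = derive_study_seed(master_seed, 3))
  subs <- make_submissions(net, lat, n_subs = 210, overlap_rate = 0.19,
                           noise_sigma = noise_sigma,
                           seed = derive_study_seed(master_seed, 4))
  d <- distance_matrix(net)
  r <- glepo_aggregate(subs, dist = d, threshold = 1000, iterations = 30,
                       seed = derive_study_seed(master_seed, 5))
  out <- list(consistency = consistency_pct(subs, r),
              spearman = cor(r$score, lat[r$node_id], method = "spearman"))
  .study_cache[[key]] <- out
  out
}

derive_study_seed <- function(seed, i) as.integer((seed * 131 + i * 17) %% 2147483647)
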