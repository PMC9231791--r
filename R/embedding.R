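#' Node embeddings for road networks
#'
#' Produces a fixed-dimension real vector per node capturing structural
#' similarity in the road graph. The default `"walk"` backend follows the
#' node2vec recipe up to the factorisation step: biased second-order random
#' walks (return parameter `p`, in-out parameter `q`) are sampled from every
#' node, co-occurrences within a sliding window are pooled into a positive
#' pointwise-mutual-information matrix, and its truncated SVD gives the
#' embedding (the standard matrix-factorisation formulation of skip-gram
#' embeddings). The `"spectral"` backend returns normalised-Laplacian
#' eigenvectors and is fully deterministic, which makes it convenient for
#' exact-reproducibility checks.
#'
#' Embeddings are not canonical across backends or hyper-parameters: only
#' properties (shape, seed-determinism, locality) are stable, never exact
#' values.
#'
#' @param net a connected `road_network`
#' @param dims embedding dimension (default 128). For the `"walk"` backend a
#'   `dims` larger than the number of nodes is allowed (extra columns are
#'   zero); the `"spectral"` backend errors in that case.
#' @param walk_length,walks_per_node,window random-walk corpus parameters.
#' @param p,q node2vec return / in-out bias parameters (1 = unbiased).
#' @param seed integer seed; same seed gives an identical matrix.
#' @param backend `"walk"` (default) or `"spectral"`.
#' @return numeric matrix (nodes x dims), rownames = node ids
#' @export
embed_nodes <- function(net, dims = 128L, walk_length = 30L,
                        walks_per_node = 10L, window = 5L, p = 1, q = 1,
                        seed = 1L, backend = c("walk", "spectral")) {
  backend <- match.arg(backend)
  stopifnot(inherits(net, "road_network"))
  if (dims < 1L) stopf("dims must be >= 1")
  g <- as_igraph(net)
  if (igraph::components(g)$no > 1L) stopf("embedding requires a connected network")
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name

  if (backend == "spectral") {
    if (dims > n) stopf("spectral backend cannot produce dims (%d) > |V| (%d)", dims, n)
    emb <- spectral_embedding(g, dims)
  } else {
    emb <- walk_embedding(g, dims, walk_length, walks_per_node, window, p, q, seed)
  }
  rownames(emb) <- ids
  colnames(emb) <- paste0("e", seq_len(ncol(emb)) - 1L)
  emb[net$nodes$node_id, , drop = FALSE]
}

# normalised-Laplacian eigenvector embedding (deterministic)
spectral_embedding <- function(g, dims) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- rowSums(A)
  dinv <- 1 / sqrt(pmax(d, 1e-12))
  L <- diag(nrow(A)) - (dinv * A) %*% diag(dinv)
  eig <- eigen(L, symmetric = TRUE)
  # smallest non-trivial eigenvectors carry the coarse structure
  idx <- order(eig$values)[seq_len(dims)]
  emb <- eig$vectors[, idx, drop = FALSE]
  # fix signs so the result does not depend on LAPACK sign conventions
  for (j in seq_len(ncol(emb))) {
    k <- which.max(abs(emb[, j]))
    if (emb[k, j] < 0) emb[, j] <- -emb[, j]
  }
  emb
}

# random-walk corpus -> windowed co-occurrence -> PPMI -> truncated SVD
walk_embedding <- function(g, dims, walk_length, walks_per_node, window, p, q,
                           seed) {
  set.seed(as.integer(seed))
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  pair_chunks <- vector("list", walks_per_node * n)
  chunk <- 0L
  for (rep in seq_len(walks_per_node)) {
    for (start in seq_len(n)) {
      walk <- random_walk_from(adj, start, walk_length, p, q)
      L <- length(walk)
      ks <- seq_len(max(min(window, L - 1L), 0L))
      pieces <- lapply(ks, function(k) {
        a <- walk[seq_len(L - k)]
        b <- walk[seq_len(L - k) + k]
        # both directions so the count matrix is symmetric
        (c(a, b) - 1) * n + c(b, a)
      })
      chunk <- chunk + 1L
      pair_chunks[[chunk]] <- unlist(pieces)
    }
  }
  C <- matrix(tabulate(unlist(pair_chunks), nbins = n * n), n, n)
  tot <- sum(C)
  rs <- rowSums(C)
  denom <- (rs %o% rs) / tot
  ratio <- ifelse(denom > 0, (C / denom), 0)
  ppmi <- log(pmax(ratio, 1))
  sv <- svd(ppmi)
  k <- min(dims, n)
  emb <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(k)]), k)
  if (dims > n) emb <- cbind(emb, matrix(0, n, dims - n))
  emb
}

# one second-order biased random walk (node2vec); p = q = 1 degenerates to a
# simple random walk and skips the bias bookkeeping
random_walk_from <- function(adj, start, walk_length, p, q) {
  walk <- integer(walk_length)
  walk[1L] <- start
  cur <- start
  prev <- 0L
  for (step in seq_len(walk_length - 1L)) {
    nbrs <- adj[[cur]]
    if (!length(nbrs)) return(walk[seq_len(step)])
    if (p == 1 && q == 1 || prev == 0L) {
      nxt <- nbrs[sample.int(length(nbrs), 1L)]
    } else {
      w <- vapply(nbrs, function(x) {
        if (x == prev) 1 / p
        else if (x %in% adj[[prev]]) 1
        else 1 / q
      }, numeric(1))
      nxt <- nbrs[sample.int(length(nbrs), 1L, prob = w)]
    }
    prev <- cur
    cur <- nxt
    walk[step + 1L] <- cur
  }
  walk
}
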