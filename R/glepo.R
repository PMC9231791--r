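#' GLEPO: aggregating relative rankings into a global order
#'
#' GLEPO (generalized linear extension of partial orders) converts a
#' collection of overlapping 5-location relative rankings into one global
#' total order. Each single run ([glepo_run()]) shuffles the submissions,
#' seeds the global list with the first one, and inserts every later
#' submission either relative to its *anchor nodes* (nodes already present
#' in the list) or, when it shares no node with the list, through a
#' geographic *virtual link*. Because insertion positions are randomized,
#' the algorithm is run many times and the per-node positions averaged
#' ([glepo_aggregate()]); the mean-position order is the final ranking and
#' is min-max normalized to a 0-100 walkability score.
#'
#' @name glepo
NULL

#' Detect anchor nodes of a submission
#'
#' Anchors are the submission's nodes that already appear in the current
#' sorted global list.
#'
#' @param sub character vector of node ids (one submission, ascending
#'   walkability).
#' @param sorted_entries character vector: current global list.
#' @return data.frame with columns `node`, `sub_pos` (position within the
#'   submission) and `sorted_pos` (position within `sorted_entries`), in
#'   submission order; zero rows when the submission is constraint-free.
#' @export
detect_anchors <- function(sub, sorted_entries) {
  hit <- which(sub %in% sorted_entries)
  data.frame(node = sub[hit], sub_pos = hit,
             sorted_pos = match(sub[hit], sorted_entries),
             stringsAsFactors = FALSE)
}

#' Randomized order-preserving insertion
#'
#' Inserts `elements` into the stretch of `sorted_entries` delimited by the
#' boundary positions `min_pos` and `max_pos` (0 = before the first entry,
#' `length(sorted_entries)` = after the last). The insertion is a uniform
#' random order-preserving merge: the relative order of `elements` and the
#' relative order of the pre-existing entries are both preserved, and no
#' element lands outside the boundary range. Uses the current RNG state.
#'
#' @param sorted_entries current global list (character).
#' @param min_pos,max_pos integer boundaries, `0 <= min_pos <= max_pos <=
#'   length(sorted_entries)`.
#' @param elements character vector of new ids (non-empty).
#' @return updated character vector
#' @export
randomized_insertion <- function(sorted_entries, min_pos, max_pos, elements) {
  L <- length(sorted_entries)
  if (min_pos < 0 || max_pos < min_pos || max_pos > L)
    stopf("invalid insertion range [%d, %d] for a list of length %d",
          min_pos, max_pos, L)
  if (!length(elements)) stopf("`elements` must be non-empty")
  region <- if (max_pos > min_pos) sorted_entries[(min_pos + 1L):max_pos] else character(0)
  k <- length(elements); m <- length(region)
  slots <- sort(sample.int(k + m, k))
  merged <- character(k + m)
  merged[slots] <- elements
  if (m) merged[-slots] <- region
  c(if (min_pos > 0L) sorted_entries[seq_len(min_pos)],
    merged,
    if (max_pos < L) sorted_entries[(max_pos + 1L):L])
}

# range insertion with degenerate-range repair: when two anchors' sorted
# positions contradict the submission order the bounds cross; the segment is
# then inserted between the crossed bounds and a conflict is flagged
insert_range <- function(sorted_entries, lo, hi, elements) {
  conflict <- 0L
  if (lo > hi) {
    tmp <- lo; lo <- hi; hi <- tmp
    conflict <- 1L
  }
  lo <- max(0L, lo); hi <- min(length(sorted_entries), hi)
  list(sorted = randomized_insertion(sorted_entries, lo, hi, elements),
       conflict = conflict)
}

#' Insert an anchored submission into the global list
#'
#' Implements the anchored-insertion case rules. With a single anchor at the
#' start (end) of the submission, the remaining four nodes are randomly
#' inserted after (before) the anchor's position in the global list. A last
#' anchor in the submission's interior splits the remaining nodes into a
#' left segment (inserted between the previous bound and the anchor) and a
#' right segment (inserted after the anchor). Any other anchor inserts the
#' segment between the running pointer and itself into the range between
#' the previous anchor's position and its own, then advances the pointer.
#' Contradictory anchor positions (a crossed range) are repaired by
#' inserting between the crossed bounds; each repair increments the
#' `conflicts` attribute of the result.
#'
#' @param sub character vector: the submission (ascending walkability).
#' @param anchors data.frame as returned by [detect_anchors()]; at least
#'   one row.
#' @param sorted_entries current global list.
#' @return updated global list with integer attribute `conflicts`
#' @export
add_to_sorted <- function(sub, anchors, sorted_entries) {
  if (!nrow(anchors)) stopf("add_to_sorted needs at least one anchor")
  g <- length(sub)
  n_anchor <- nrow(anchors)
  conflicts <- 0L
  ptr <- 1L          # first unplaced submission position
  prev_bound <- 0L   # boundary just after the previously processed anchor
  for (ai in seq_len(n_anchor)) {
    a_sub <- anchors$sub_pos[ai]
    a_sorted <- match(anchors$node[ai], sorted_entries)
    only <- n_anchor == 1L
    last <- ai == n_anchor
    L <- length(sorted_entries)
    if (only && a_sub == 1L) {
      sorted_entries <- randomized_insertion(sorted_entries, a_sorted, L, sub[-1L])
    } else if (only && a_sub == g) {
      sorted_entries <- randomized_insertion(sorted_entries, 0L, a_sorted - 1L,
                                             sub[-g])
    } else if (last && a_sub > 1L && a_sub < g) {
      if (ptr <= a_sub - 1L) {
        res <- insert_range(sorted_entries, prev_bound, a_sorted - 1L,
                            sub[ptr:(a_sub - 1L)])
        sorted_entries <- res$sorted
        conflicts <- conflicts + res$conflict
        a_sorted <- match(anchors$node[ai], sorted_entries)
      }
      sorted_entries <- randomized_insertion(sorted_entries, a_sorted,
                                             length(sorted_entries),
                                             sub[(a_sub + 1L):g])
    } else {
      if (ptr <= a_sub - 1L) {
        res <- insert_range(sorted_entries, prev_bound, a_sorted - 1L,
                            sub[ptr:(a_sub - 1L)])
        sorted_entries <- res$sorted
        conflicts <- conflicts + res$conflict
      }
      ptr <- a_sub + 1L
      prev_bound <- match(anchors$node[ai], sorted_entries)
    }
  }
  attr(sorted_entries, "conflicts") <- conflicts
  sorted_entries
}

#' Insert a constraint-free submission via a geographic virtual link
#'
#' Finds the globally nearest pair between the current global list and the
#' submission's nodes. If that distance is below `threshold` metres, the
#' nearest submission node is placed next to the nearest sorted node and
#' then treated as an anchor for [add_to_sorted()], creating an artificial
#' order constraint out of geographic proximity. Otherwise the whole
#' submission is randomly inserted over the full list range with its
#' internal order preserved.
#'
#' @param sub character vector: a submission with no anchors in the list.
#' @param sorted_entries current global list (non-empty).
#' @param dist a [distance_matrix()] covering all involved node ids.
#' @param threshold virtual-link distance threshold in metres.
#' @return updated global list with attribute `vlink` set to `"anchored"`
#'   or `"fallback"` (and `conflicts` from the anchored path)
#' @export
virtual_link <- function(sub, sorted_entries, dist, threshold = 1000) {
  if (!length(sorted_entries)) stopf("`sorted_entries` must be non-empty")
  ids <- c(sorted_entries, sub)
  missing <- setdiff(ids, rownames(dist))
  if (length(missing))
    stopf("distance matrix lacks node(s): %s", paste(head(missing, 5), collapse = ", "))
  D <- dist[sorted_entries, sub, drop = FALSE]
  best <- arrayInd(which.min(D), dim(D))
  if (D[best] < threshold) {
    i <- best[1L]; j <- best[2L]
    sorted_entries <- append(sorted_entries, sub[j], after = i)
    anchors <- data.frame(node = sub[j], sub_pos = j,
                          sorted_pos = i + 1L, stringsAsFactors = FALSE)
    out <- add_to_sorted(sub, anchors, sorted_entries)
    attr(out, "vlink") <- "anchored"
    out
  } else {
    out <- randomized_insertion(sorted_entries, 0L, length(sorted_entries), sub)
    attr(out, "vlink") <- "fallback"
    attr(out, "conflicts") <- 0L
    out
  }
}

#' One randomized GLEPO run
#'
#' Shuffles the submission processing order, appends the first submission
#' verbatim, and routes every later submission to [add_to_sorted()] (when
#' anchors are found) or [virtual_link()] (when constraint-free). With
#' `dist = NULL` virtual links are disabled and constraint-free submissions
#' fall back to full-range randomized insertion.
#'
#' @param subs a `submission_set`
#' @param dist optional [distance_matrix()] enabling virtual links.
#' @param threshold virtual-link threshold in metres.
#' @param seed optional integer seed for this run.
#' @return character vector: a permutation of all unique submitted nodes
#'   (ascending walkability), with attributes `conflicts`, `vlink_anchored`
#'   and `vlink_fallback`
#' @export
glepo_run <- function(subs, dist = NULL, threshold = 1000, seed = NULL) {
  stopifnot(inherits(subs, "submission_set"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  order_idx <- sample.int(length(subs$nodes))
  sorted <- character(0)
  conflicts <- 0L; n_anch <- 0L; n_fall <- 0L
  for (j in order_idx) {
    sub <- subs$nodes[[j]]
    if (!length(sorted)) {
      sorted <- sub
      next
    }
    anchors <- detect_anchors(sub, sorted)
    if (nrow(anchors)) {
      sorted <- add_to_sorted(sub, anchors, sorted)
      conflicts <- conflicts + (attr(sorted, "conflicts") %||% 0L)
    } else if (!is.null(dist)) {
      sorted <- virtual_link(sub, sorted, dist, threshold)
      conflicts <- conflicts + (attr(sorted, "conflicts") %||% 0L)
      if (identical(attr(sorted, "vlink"), "anchored")) n_anch <- n_anch + 1L
      else n_fall <- n_fall + 1L
    } else {
      sorted <- randomized_insertion(sorted, 0L, length(sorted), sub)
      n_fall <- n_fall + 1L
    }
  }
  out <- as.character(sorted)
  attr(out, "conflicts") <- conflicts
  attr(out, "vlink_anchored") <- n_anch
  attr(out, "vlink_fallback") <- n_fall
  out
}

#' Aggregate GLEPO runs into a global ranking
#'
#' Runs [glepo_run()] `iterations` times with seeds derived from the master
#' seed, records each node's 0-based position in every run, and orders
#' nodes by mean position (ties broken by node id, so results are exactly
#' reproducible). Scores are the min-max normalization of mean positions
#' onto 0-100: a node appearing later in the list (more walkable) scores
#' higher.
#'
#' @param subs a `submission_set`
#' @param dist optional [distance_matrix()] enabling virtual links.
#' @param threshold virtual-link threshold in metres (default 1000).
#' @param iterations number of randomized runs to average (>= 1; 30 is
#'   where the aggregated list typically stabilizes).
#' @param seed master integer seed.
#' @return object of class `glepo_ranking`: a data.frame with columns
#'   `node_id`, `mean_position`, `rank` (1 = least walkable) and `score`
#'   (0-100), ordered by rank; attributes `positions` (iterations x nodes
#'   matrix), `conflicts`, `vlink_anchored`, `vlink_fallback`
#' @export
glepo_aggregate <- function(subs, dist = NULL, threshold = 1000,
                            iterations = 30L, seed = 1L) {
  stopifnot(inherits(subs, "submission_set"))
  if (iterations < 1L) stopf("iterations must be >= 1")
  all_nodes <- sort(submitted_nodes(subs))
  pos <- matrix(NA_real_, nrow = iterations, ncol = length(all_nodes),
                dimnames = list(NULL, all_nodes))
  conflicts <- 0L; n_anch <- 0L; n_fall <- 0L
  for (t in seq_len(iterations)) {
    run <- glepo_run(subs, dist = dist, threshold = threshold,
                     seed = derive_seed(seed, t))
    pos[t, ] <- match(all_nodes, run) - 1
    conflicts <- conflicts + attr(run, "conflicts")
    n_anch <- n_anch + attr(run, "vlink_anchored")
    n_fall <- n_fall + attr(run, "vlink_fallback")
  }
  mean_pos <- colMeans(pos)
  ord <- order(mean_pos, all_nodes)
  out <- data.frame(node_id = all_nodes[ord],
                    mean_position = mean_pos[ord],
                    rank = seq_along(ord),
                    score = ranks_to_scores(mean_pos[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("glepo_ranking", "data.frame"),
            positions = pos, conflicts = conflicts,
            vlink_anchored = n_anch, vlink_fallback = n_fall,
            iterations = iterations, seed = seed)
}

#' @export
print.glepo_ranking <- function(x, ...) {
  cat(sprintf("<glepo_ranking> %d nodes, %d iterations (conflicts: %d, virtual links: %d anchored / %d fallback)\n",
              nrow(x), attr(x, "iterations") %||% NA,
              attr(x, "conflicts") %||% 0L,
              attr(x, "vlink_anchored") %||% 0L,
              attr(x, "vlink_fallback") %||% 0L))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Normalize mean positions to 0-100 walkability scores
#'
#' Min-max normalization: the node with the smallest mean position (least
#' walkable) scores 0, the largest scores 100, equal mean positions map to
#' equal scores. If all positions are identical every node scores 50, with
#' a warning.
#'
#' @param x a `glepo_ranking` or a numeric vector of mean positions.
#' @return numeric vector of scores in \[0, 100\]
#' @export
ranks_to_scores <- function(x) {
  mp <- if (inherits(x, "glepo_ranking")) x$mean_position else as.numeric(x)
  rng <- range(mp)
  if (diff(rng) == 0) {
    warnf("all mean positions identical; assigning score 50 to every node")
    return(rep(50, length(mp)))
  }
  100 * (mp - rng[1]) / (rng[2] - rng[1])
}

#' Convergence trace of aggregated GLEPO runs
#'
#' Spearman rank correlation between the cumulative-mean position vectors
#' after t and after t-1 runs, for t = 2..T. A series settling at 1
#' indicates the aggregated order has converged.
#'
#' @param x a `glepo_ranking` (uses its stored per-run positions) or a
#'   numeric matrix of per-run positions (runs x nodes).
#' @return numeric vector of length T-1
#' @export
convergence_trace <- function(x) {
  pos <- if (inherits(x, "glepo_ranking")) attr(x, "positions") else as.matrix(x)
  if (is.null(pos) || nrow(pos) < 2L) stopf("need at least 2 runs for a trace")
  cum <- apply(pos, 2, cumsum) / seq_len(nrow(pos))
  vapply(2:nrow(pos), function(t) {
    suppressWarnings(cor(cum[t, ], cum[t - 1L, ], method = "spearman"))
  }, numeric(1))
}

#' Write a global ranking as CSV
#' @param ranking a `glepo_ranking`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_ranking_csv <- function(ranking, file) {
  write.csv(as.data.frame(ranking), file, row.names = FALSE)
  invisible(file)
}
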