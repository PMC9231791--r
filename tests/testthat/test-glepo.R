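test_that("anchor detection finds shared nodes in submission order", {
  sorted <- c("n1", "n2", "n3", "n4", "n5")
  hits <- detect_anchors(c("n6", "n7", "n3", "n8", "n9"), sorted)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$node, "n3")
  expect_equal(hits$sub_pos, 3L)
  expect_equal(hits$sorted_pos, 3L)
  expect_equal(nrow(detect_anchors(c("a", "b", "c", "d", "e"), sorted)), 0L)
  all5 <- detect_anchors(c("n5", "n1", "n3", "n2", "n4"), sorted)
  expect_equal(all5$node, c("n5", "n1", "n3", "n2", "n4"))
})

test_that("randomized insertion preserves both orders and stays in range", {
  expect_equal(randomized_insertion(character(0), 0, 0, c("a", "b")),
               c("a", "b"))
  base <- c("x", "y", "z")
  for (s in 1:200) {
    set.seed(s)
    out <- randomized_insertion(base, 1, 3, c("a", "b"))
    expect_length(out, 5L)
    expect_true(is_subsequence(c("a", "b"), out))
    expect_true(is_subsequence(base, out))
    expect_equal(out[1], "x")               # insertions confined to (1,3]
  }
  # more elements than the range holds: interleaving still order-preserving
  for (s in 1:50) {
    set.seed(s)
    out <- randomized_insertion(base, 1, 2, c("e1", "e2", "e3", "e4", "e5"))
    expect_length(out, 8L)
    expect_true(is_subsequence(c("e1", "e2", "e3", "e4", "e5"), out))
    expect_true(is_subsequence(base, out))
    expect_equal(out[1], "x")
    expect_equal(out[8], "z")
  }
  expect_error(randomized_insertion(base, 2, 1, "a"), "range")
  expect_error(randomized_insertion(base, 0, 4, "a"), "range")
  expect_error(randomized_insertion(base, 0, 3, character(0)), "non-empty")
})

test_that("anchored insertion follows the case rules", {
  # middle anchor: left half before it, right half after it
  for (s in 1:100) {
    set.seed(s)
    sorted <- c("n1", "n2", "n3", "n4", "n5")
    sub <- c("n6", "n7", "n3", "n8", "n9")
    out <- add_to_sorted(sub, detect_anchors(sub, sorted), sorted)
    p <- match(c("n6", "n7", "n3", "n8", "n9"), out)
    expect_true(all(p[1:2] < p[3]) && all(p[4:5] > p[3]))
    expect_true(is_subsequence(sorted, out))
    expect_setequal(out, union(sorted, sub))
  }
  # single anchor at submission start: the rest lands after it, in order
  for (s in 1:100) {
    set.seed(s)
    out <- add_to_sorted(c("x", "a", "b", "c", "d"),
                         detect_anchors(c("x", "a", "b", "c", "d"),
                                        c("x", "y", "z")),
                         c("x", "y", "z"))
    p <- match(c("x", "a", "b", "c", "d"), out)
    expect_true(all(p[-1] > p[1]))
    expect_true(all(diff(p[-1]) > 0))
  }
  # single anchor at submission end: the rest lands before it, in order
  for (s in 1:100) {
    set.seed(s)
    out <- add_to_sorted(c("a", "b", "c", "d", "z"),
                         detect_anchors(c("a", "b", "c", "d", "z"),
                                        c("x", "y", "z")),
                         c("x", "y", "z"))
    p <- match(c("a", "b", "c", "d", "z"), out)
    expect_true(all(p[1:4] < p[5]))
    expect_true(all(diff(p[1:4]) > 0))
  }
  # contradicting anchors are repaired and counted as conflicts
  set.seed(1)
  sorted <- c("q", "p", "r")       # p and q inverted w.r.t. the submission
  sub <- c("p", "m1", "q", "m2", "m3")
  out <- add_to_sorted(sub, detect_anchors(sub, sorted), sorted)
  expect_gte(attr(out, "conflicts"), 1L)
  expect_setequal(out, union(sorted, sub))
})

test_that("virtual link anchors nearby submissions and falls back when far", {
  nodes <- data.frame(
    node_id = c("s1", "s2", "s3", "a", "b", "c", "d", "e"),
    lat = c(47.500, 47.501, 47.502, 47.5025, 47.60, 47.61, 47.62, 47.63),
    lon = -52.7)
  net <- road_network(nodes, data.frame(u = nodes$node_id[-8],
                                        v = nodes$node_id[-1]))
  d <- distance_matrix(net)
  sorted <- c("s1", "s2", "s3")
  sub <- c("a", "b", "c", "d", "e")   # "a" is ~55 m from s3; rest far north
  set.seed(2)
  out <- virtual_link(sub, sorted, d, threshold = 1000)
  expect_identical(attr(out, "vlink"), "anchored")
  expect_setequal(out, c(sorted, sub))
  expect_true(is_subsequence(sorted, out))
  # threshold 0 forces the full-range fallback with internal order intact
  for (s in 1:50) {
    set.seed(s)
    out0 <- virtual_link(sub, sorted, d, threshold = 0)
    expect_identical(attr(out0, "vlink"), "fallback")
    expect_true(is_subsequence(sub, out0))
    expect_true(is_subsequence(sorted, out0))
  }
  expect_error(virtual_link(c("zz", sub[-1]), sorted, d, 1000), "zz")
})

test_that("single runs are valid linear extensions of the fixtures", {
  fix <- verification_fixtures()
  expect_equal(glepo_run(submission_set(list(c("a", "b", "c", "d", "e"))),
                         seed = 1),
               c("a", "b", "c", "d", "e"), ignore_attr = TRUE)

  ext <- valid_extensions(fix$extremes)
  expect_length(ext, 20L)
  keys <- vapply(ext, paste, character(1), collapse = ",")
  for (s in 1:200) {
    out <- glepo_run(fix$extremes, seed = s)
    expect_true(paste(out, collapse = ",") %in% keys)
    expect_equal(out[1], "1")
    expect_equal(out[length(out)], "5")
  }
  # every run on every fixture is a permutation of the submitted nodes
  for (nm in names(fix)) {
    for (s in 1:20) {
      out <- glepo_run(fix[[nm]], seed = 300 + s)
      expect_setequal(out, submitted_nodes(fix[[nm]]))
      expect_equal(length(out), length(unique(out)))
    }
  }
})

test_that("disjoint far-apart submissions keep their internal order", {
  nodes <- data.frame(node_id = c(paste0("a", 1:5), paste0("b", 1:5)),
                      lat = c(seq(47.5, 47.504, by = 0.001),
                              seq(48.5, 48.504, by = 0.001)),
                      lon = -52.7)
  net <- road_network(nodes, data.frame(u = nodes$node_id[-10],
                                        v = nodes$node_id[-1]))
  d <- distance_matrix(net)
  subs <- submission_set(list(paste0("a", 1:5), paste0("b", 1:5)))
  for (s in 1:100) {
    out <- glepo_run(subs, dist = d, threshold = 1000, seed = s)
    expect_true(is_subsequence(paste0("a", 1:5), out))
    expect_true(is_subsequence(paste0("b", 1:5), out))
    expect_equal(submission_loss(paste0("a", 1:5), out), 0)
    expect_equal(submission_loss(paste0("b", 1:5), out), 0)
  }
})

test_that("aggregation averages positions, ranks extremes correctly, breaks ties stably", {
  fix <- verification_fixtures()
  one <- glepo_aggregate(fix$extremes, iterations = 1, seed = 7)
  run1 <- glepo_run(fix$extremes, seed = alfscore:::derive_seed(7, 1))
  expect_equal(one$node_id[order(one$rank)][one$rank], one$node_id)
  expect_equal(one$node_id, as.character(run1), ignore_attr = TRUE)

  agg <- glepo_aggregate(fix$extremes, iterations = 30, seed = 11)
  expect_equal(agg$node_id[which.min(agg$mean_position)], "1")
  expect_equal(agg$node_id[which.max(agg$mean_position)], "5")
  expect_equal(sort(agg$node_id), sort(submitted_nodes(fix$extremes)))

  # exchange symmetry of the two interior chains over many iterations
  agg200 <- glepo_aggregate(fix$extremes, iterations = 200, seed = 13)
  mp <- setNames(agg200$mean_position, agg200$node_id)
  expect_lt(abs(mp["2"] - mp["6"]), 1.0)

  # reproducibility of the whole aggregate
  expect_equal(as.data.frame(glepo_aggregate(fix$extremes, iterations = 10, seed = 5)),
               as.data.frame(glepo_aggregate(fix$extremes, iterations = 10, seed = 5)))
})

test_that("scores normalize mean positions onto 0-100", {
  expect_equal(ranks_to_scores(c(3, 9)), c(0, 100))
  sc <- ranks_to_scores(c(5, 1, 3, 10))
  expect_equal(min(sc), 0)
  expect_equal(max(sc), 100)
  expect_equal(sc[2], 0)
  # ties in mean position map to equal scores
  sc2 <- ranks_to_scores(c(1, 2, 2, 4))
  expect_equal(sc2[2], sc2[3])
  expect_warning(flat <- ranks_to_scores(c(2, 2, 2)), "identical")
  expect_equal(flat, rep(50, 3))
  agg <- glepo_aggregate(verification_fixtures()$extremes, iterations = 5, seed = 1)
  expect_true(all(agg$score >= 0 & agg$score <= 100))
})

test_that("convergence trace flags stable and unstable run sequences", {
  pos <- matrix(rep(0:4, each = 6), nrow = 6)   # identical runs
  expect_equal(convergence_trace(pos), rep(1, 5))

  agg <- glepo_aggregate(verification_fixtures()$extremes,
                         iterations = 50, seed = 3)
  tr <- convergence_trace(agg)
  expect_length(tr, 49L)
  expect_gte(tr[49], tr[1] - 0.05)

  # alternating reversed orders never settle into correlation 1 throughout
  alt <- do.call(rbind, rep(list(0:5, 5:0), 5))
  tra <- convergence_trace(alt)
  expect_false(isTRUE(all(tra == 1)))
  expect_error(convergence_trace(matrix(0:4, nrow = 1)), "2 runs")
})
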