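test_that("CSV reader builds a path network and validates input", {
  nd <- tempfile(fileext = ".csv"); ed <- tempfile(fileext = ".csv")
  writeLines(c("node_id,lat,lon", "a,47.5,-52.7", "b,47.501,-52.7",
               "c,47.502,-52.7"), nd)
  writeLines(c("u,v", "a,b", "b,c"), ed)
  net <- read_network_csv(nd, ed)
  expect_s3_class(net, "road_network")
  expect_equal(n_nodes(net), 3L)
  expect_equal(nrow(net$edges), 2L)

  expect_error(road_network(data.frame(node_id = c("a", "a"), lat = 0, lon = 0),
                            data.frame(u = "a", v = "a")), "duplicate")
  expect_error(road_network(data.frame(node_id = c("a", "b"),
                                       lat = c(95, 0), lon = 0),
                            data.frame(u = "a", v = "b")), "90")
  expect_error(road_network(data.frame(node_id = c("a", "b"), lat = 0, lon = 0),
                            data.frame(u = "a", v = "a")), "self-loop")
  expect_error(road_network(data.frame(node_id = c("a", "b"), lat = 0, lon = 0),
                            data.frame(u = "a", v = "z")), "z")
})

test_that("OSM reader keeps only whitelisted highway ways", {
  osm <- tempfile(fileext = ".osm")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<osm>',
    ' <node id="1" lat="47.50" lon="-52.70"/>',
    ' <node id="2" lat="47.51" lon="-52.70"/>',
    ' <node id="3" lat="47.52" lon="-52.70"/>',
    ' <node id="4" lat="47.53" lon="-52.70"/>',
    ' <node id="5" lat="47.54" lon="-52.70"/>',
    ' <way id="10"><nd ref="1"/><nd ref="2"/><nd ref="3"/><tag k="highway" v="residential"/></way>',
    ' <way id="11"><nd ref="4"/><nd ref="5"/><tag k="waterway" v="river"/></way>',
    '</osm>'), osm)
  net <- read_network_osm(osm)
  expect_equal(sort(net$nodes$node_id), c("1", "2", "3"))
  expect_equal(nrow(net$edges), 2L)

  # nothing matching the whitelist -> explicit error
  osm2 <- tempfile(fileext = ".osm")
  writeLines(c('<osm><node id="1" lat="0" lon="0"/>',
               '<way id="9"><nd ref="1"/><tag k="waterway" v="river"/></way></osm>'),
             osm2)
  expect_error(read_network_osm(osm2), "empty graph")
  expect_error(read_network_osm(textConnection("not xml <<")), "parse")
})

test_that("disconnected input keeps the largest component with a warning", {
  ids <- letters[1:7]
  edges <- data.frame(u = c("a", "b", "c", "d", "f"),
                      v = c("b", "c", "d", "e", "g"))
  nodes <- data.frame(node_id = ids, lat = seq(0, 0.006, by = 0.001), lon = 0)
  expect_warning(net <- road_network(nodes, edges), "largest component")
  expect_equal(sort(net$nodes$node_id), c("a", "b", "c", "d", "e"))
  expect_error(road_network(nodes, edges, require_connected = TRUE),
               "disconnected")
})

test_that("haversine distance: identity, symmetry, known equator arc", {
  expect_equal(haversine_distance(12.3, 45.6, 12.3, 45.6), 0)
  # closed form: one degree along the equator on an R = 6371000 m sphere
  expect_equal(haversine_distance(0, 0, 0, 1), 6371000 * pi / 180,
               tolerance = 1e-9)
  set.seed(7)
  for (i in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -170, 170))
    b <- c(runif(1, -80, 80), runif(1, -170, 170))
    expect_equal(haversine_distance(a[1], a[2], b[1], b[2]),
                 haversine_distance(b[1], b[2], a[1], a[2]))
  }
  expect_error(haversine_distance(100, 0, 0, 0), "range")
})

test_that("distance matrix matches pairwise calls and metric axioms", {
  nodes <- data.frame(node_id = c("a", "b", "c"),
                      lat = c(47.5, 47.6, 47.55), lon = c(-52.7, -52.8, -52.6))
  net <- road_network(nodes, data.frame(u = c("a", "b"), v = c("b", "c")))
  d <- distance_matrix(net)
  expect_equal(dim(d), c(3L, 3L))
  expect_equal(diag(d), setNames(rep(0, 3), nodes$node_id))
  expect_equal(d, t(d))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(d[i, j],
                 haversine_distance(nodes$lat[i], nodes$lon[i],
                                    nodes$lat[j], nodes$lon[j]),
                 tolerance = 1e-6)
  }
  # triangle inequality on random triples of a bigger random layout
  set.seed(11)
  big <- road_network(data.frame(node_id = sprintf("r%02d", 1:15),
                                 lat = runif(15, 47, 48),
                                 lon = runif(15, -53, -52)),
                      data.frame(u = sprintf("r%02d", 1:14),
                                 v = sprintf("r%02d", 2:15)))
  db <- distance_matrix(big)
  for (k in 1:50) {
    ijk <- sample(15, 3)
    expect_lte(db[ijk[1], ijk[3]],
               db[ijk[1], ijk[2]] + db[ijk[2], ijk[3]] + 1e-6)
  }
  # quadratic size contract: doubling n quadruples the entry count
  expect_equal(length(distance_matrix(path_net(20))) /
                 length(distance_matrix(path_net(10))), 4)
  expect_error(distance_matrix(big, max_nodes = 10), "cap")
})

test_that("path and star centralities match hand-enumerated values", {
  cp <- compute_centralities(path_net(3, c("a", "b", "c")))
  expect_equal(cp["b", "degree"], 2)
  expect_equal(cp["a", "degree"], 1)
  expect_equal(cp["b", "betweenness"], 1)      # only interior vertex
  expect_equal(cp["a", "eccentricity"], 2)
  expect_equal(cp["b", "stress"], 1)           # one path a-b-c
  expect_equal(unname(cp[, "betweenness"][cp[, "degree"] == 1]), c(0, 0))

  cs <- compute_centralities(star_net(3))
  expect_equal(cs["c", "closeness"], 1)
  expect_equal(cs["c", "clustering_coefficient"], 0)
  expect_equal(cs["l1", "neighborhood_connectivity"], 3)

  # a hand-assembled disconnected object must be rejected
  g2 <- structure(list(nodes = data.frame(node_id = letters[1:4],
                                          lat = c(0, 0.001, 0.002, 0.003),
                                          lon = 0),
                       edges = data.frame(u = c("a", "c"), v = c("b", "d"))),
                  class = "road_network")
  expect_error(compute_centralities(g2), "connected")
})

test_that("all 8 centralities agree with the brute-force oracle on random graphs", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(5:12, 1)
    rg <- random_connected_graph(n, seed = 100 + s)
    got <- compute_centralities(rg$net)
    want <- oracle_centralities(rg$A)
    rownames(want) <- rg$ids
    expect_equal(unclass(got)[rg$ids, ], want, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(got[, "stress"] >= 0))
    expect_true(all(got[got[, "degree"] == 1, "betweenness"] == 0))
    expect_true(all(got[, "eccentricity"] <= n - 1))
  }
})
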