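#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by the `run_*` pipeline
#' commands (and by the `alfscore` command-line script, a thin wrapper over
#' them). Unknown fields are rejected so typos fail fast. All randomness in
#' a pipeline run flows from the single `seed` field.
#'
#' @param ... configuration fields overriding the defaults, or a single
#'   named list of them.
#' @param file optional YAML file to read first; `...` overrides it.
#' @return named list of class `alf_config`
#' @export
alf_config <- function(..., file = NULL) {
  defaults <- list(
    out_dir = ".",
    seed = 1L,
    # synthetic city (defaults sized like the reference study collection)
    n_nodes = 1000L, network_kind = "grid", n_pois = 400L,
    n_subs = 210L, group_size = 5L, overlap_rate = 0.19,
    noise_sigma = 0, latent_weights = c(poi = 1, closeness = 1, field = 1),
    # inputs (read by glepo/features/train when not simulating)
    node_file = NULL, edge_file = NULL, osm_file = NULL,
    poi_file = NULL, submissions_file = NULL, labels_file = NULL,
    # POI features
    band_min = 200, band_max = 2000, band_step = 200,
    # embedding
    embedding_dims = 128L, walk_length = 30L, walks_per_node = 10L,
    window = 5L, p = 1, q = 1, embedding_backend = "walk",
    # GLEPO
    iterations = 30L, vlink_threshold = 1000, use_virtual_links = TRUE,
    # model
    technique = "random_forest", combo = "all", train_fraction = 0.8,
    kfold = NULL, grid = FALSE, model_file = NULL)
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    overrides <- utils::modifyList(from_file, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "alf_config")
}

#' Write node scores as a GeoJSON FeatureCollection
#'
#' One Point feature per node with an `alf_score` property.
#'
#' @param nodes data.frame `node_id,lat,lon`.
#' @param scores numeric scores named by node id.
#' @param file output path
#' @return `file`, invisibly
#' @export
write_scores_geojson <- function(nodes, scores, file) {
  feats <- lapply(seq_len(nrow(nodes)), function(i) {
    id <- nodes$node_id[i]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(nodes$lon[i], nodes$lat[i])),
         properties = list(node_id = id,
                           alf_score = unname(scores[[id]])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

write_manifest <- function(cfg, dir, stage, extra = list()) {
  man <- c(list(stage = stage, seed = cfg$seed,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate a synthetic city to disk
#'
#' Writes `nodes.csv`, `edges.csv`, `pois.csv`, `submissions.jsonl`,
#' `latent.csv` and a manifest into `cfg$out_dir`, using the same formats
#' the pipeline reads back, so simulated runs exercise the real I/O paths.
#'
#' @param cfg an `alf_config`
#' @return invisibly, a list with the in-memory objects
#' @export
run_simulate <- function(cfg = alf_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_network(cfg$n_nodes, cfg$network_kind, seed = cfg$seed)
  pois <- make_pois(net, cfg$n_pois, seed = derive_seed(cfg$seed, 2))
  latent <- latent_walkability(net, pois, weights = cfg$latent_weights,
                               seed = derive_seed(cfg$seed, 3))
  subs <- make_submissions(net, latent, n_subs = cfg$n_subs,
                           group_size = cfg$group_size,
                           overlap_rate = cfg$overlap_rate,
                           noise_sigma = cfg$noise_sigma,
                           seed = derive_seed(cfg$seed, 4))
  write.csv(net$nodes, file.path(cfg$out_dir, "nodes.csv"), row.names = FALSE)
  write.csv(net$edges, file.path(cfg$out_dir, "edges.csv"), row.names = FALSE)
  write.csv(pois, file.path(cfg$out_dir, "pois.csv"), row.names = FALSE)
  write_submissions(subs, file.path(cfg$out_dir, "submissions.jsonl"))
  write.csv(data.frame(node_id = names(latent), latent_score = unname(latent)),
            file.path(cfg$out_dir, "latent.csv"), row.names = FALSE)
  write_manifest(cfg, cfg$out_dir, "simulate",
                 list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
                      n_pois = nrow(pois), n_subs = length(subs)))
  invisible(list(net = net, pois = pois, latent = latent, subs = subs))
}

load_network_cfg <- function(cfg) {
  if (!is.null(cfg$osm_file)) return(read_network_osm(cfg$osm_file))
  node_file <- cfg$node_file %||% file.path(cfg$out_dir, "nodes.csv")
  edge_file <- cfg$edge_file %||% file.path(cfg$out_dir, "edges.csv")
  read_network_csv(node_file, edge_file)
}

#' Run GLEPO aggregation to disk
#'
#' Reads the network and submissions, aggregates with [glepo_aggregate()],
#' and writes `ranking.csv`, `scores.geojson` and `consistency.json`.
#'
#' @param cfg an `alf_config`
#' @return invisibly, the `glepo_ranking`
#' @export
run_glepo <- function(cfg = alf_config()) {
  net <- load_network_cfg(cfg)
  subs <- read_submissions(cfg$submissions_file %||%
                             file.path(cfg$out_dir, "submissions.jsonl"))
  missing <- setdiff(submitted_nodes(subs), net$nodes$node_id)
  if (length(missing))
    stopf("submission node(s) absent from the network: %s",
          paste(head(missing, 5), collapse = ", "))
  dist <- if (isTRUE(cfg$use_virtual_links)) distance_matrix(net) else NULL
  ranking <- glepo_aggregate(subs, dist = dist,
                             threshold = cfg$vlink_threshold,
                             iterations = cfg$iterations, seed = cfg$seed)
  write_ranking_csv(ranking, file.path(cfg$out_dir, "ranking.csv"))
  sc <- setNames(ranking$score, ranking$node_id)
  write_scores_geojson(net$nodes[net$nodes$node_id %in% names(sc), , drop = FALSE],
                       sc, file.path(cfg$out_dir, "scores.geojson"))
  rep <- consistency_report(subs, ranking)
  jsonlite::write_json(
    c(rep$summary,
      list(conflicts = attr(ranking, "conflicts"),
           vlink_anchored = attr(ranking, "vlink_anchored"),
           vlink_fallback = attr(ranking, "vlink_fallback"))),
    file.path(cfg$out_dir, "consistency.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, cfg$out_dir, "glepo",
                 list(iterations = cfg$iterations,
                      threshold = cfg$vlink_threshold,
                      consistency_pct = rep$summary$consistency_pct))
  invisible(ranking)
}

#' Extract all feature blocks to disk
#'
#' Writes `poi_features.csv`, `network_features.csv` and `embedding.csv`.
#'
#' @param cfg an `alf_config`
#' @return invisibly, the `feature_bundle`
#' @export
run_features <- function(cfg = alf_config()) {
  net <- load_network_cfg(cfg)
  poi_file <- cfg$poi_file %||% file.path(cfg$out_dir, "pois.csv")
  pois <- read_pois_csv(poi_file)
  bands <- band_grid(cfg$band_min, cfg$band_max, cfg$band_step)
  poi_f <- extract_poi_features(net, pois, bands = bands)
  cent <- compute_centralities(net)
  emb <- embed_nodes(net, dims = cfg$embedding_dims,
                     walk_length = cfg$walk_length,
                     walks_per_node = cfg$walks_per_node,
                     window = cfg$window, p = cfg$p, q = cfg$q,
                     seed = cfg$seed, backend = cfg$embedding_backend)
  write_features_csv(poi_f, file.path(cfg$out_dir, "poi_features.csv"))
  write_features_csv(unclass(cent), file.path(cfg$out_dir, "network_features.csv"))
  write_features_csv(emb, file.path(cfg$out_dir, "embedding.csv"))
  write_manifest(cfg, cfg$out_dir, "features",
                 list(poi_cols = ncol(poi_f), network_cols = ncol(cent),
                      embedding_cols = ncol(emb)))
  invisible(feature_bundle(poi_f, unclass(cent), emb))
}

read_features_csv <- function(file) {
  df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$node_id
  m
}

load_bundle_cfg <- function(cfg) {
  feature_bundle(
    poi = read_features_csv(file.path(cfg$out_dir, "poi_features.csv")),
    network = read_features_csv(file.path(cfg$out_dir, "network_features.csv")),
    embedding = read_features_csv(file.path(cfg$out_dir, "embedding.csv")))
}

load_labels_cfg <- function(cfg, bundle) {
  labels_file <- cfg$labels_file %||% file.path(cfg$out_dir, "ranking.csv")
  lab <- read.csv(labels_file, stringsAsFactors = FALSE)
  if (!all(c("node_id", "score") %in% names(lab)))
    stopf("label file needs columns node_id and score")
  ids <- rownames(bundle$poi)
  ids <- ids[ids %in% lab$node_id]
  if (!length(ids)) stopf("no labelled nodes overlap the feature matrix")
  setNames(lab$score[match(ids, lab$node_id)], ids)
}

#' Train and evaluate walkability models to disk
#'
#' With `cfg$grid = TRUE` runs the full technique-by-combination grid and
#' writes `grid.csv`; otherwise trains the single configured technique and
#' combination, writes `eval.json`, saves the model to `model.rds` and
#' records a metadata JSON.
#'
#' @param cfg an `alf_config`
#' @return invisibly, the grid data.frame or the `alf_model`
#' @export
run_train <- function(cfg = alf_config()) {
  bundle <- load_bundle_cfg(cfg)
  y_full <- load_labels_cfg(cfg, bundle)
  keep <- rownames(bundle$poi) %in% names(y_full)
  bundle <- feature_bundle(bundle$poi[keep, , drop = FALSE],
                           bundle$network[keep, , drop = FALSE],
                           bundle$embedding[keep, , drop = FALSE])
  y <- y_full[rownames(bundle$poi)]
  if (isTRUE(cfg$grid)) {
    grid <- evaluation_grid(bundle, y, train_fraction = cfg$train_fraction,
                            seed = cfg$seed)
    write.csv(grid, file.path(cfg$out_dir, "grid.csv"), row.names = FALSE)
    write_manifest(cfg, cfg$out_dir, "train", list(grid = TRUE))
    return(invisible(grid))
  }
  X <- assemble_features(bundle, cfg$combo)
  if (!is.null(cfg$kfold)) {
    cv <- kfold_cv(cfg$technique, X, y, k = cfg$kfold, seed = cfg$seed)
    jsonlite::write_json(cv$summary, file.path(cfg$out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(cfg, cfg$out_dir, "train",
                   list(technique = cfg$technique, kfold = cfg$kfold))
    return(invisible(cv))
  }
  sp <- split_data(X, y, cfg$train_fraction, seed = cfg$seed)
  model <- train_walkability(cfg$technique, sp$train$X, sp$train$y,
                             seed = cfg$seed)
  report <- evaluate_model(model, sp$test$X, sp$test$y)
  saveRDS(model, file.path(cfg$out_dir, "model.rds"))
  jsonlite::write_json(unclass(report), file.path(cfg$out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, cfg$out_dir, "train",
                 list(technique = cfg$technique, combo = cfg$combo,
                      train_fraction = cfg$train_fraction,
                      mae = report$mae, rmse = report$rmse,
                      accuracy_pct = report$accuracy_pct))
  invisible(model)
}

#' Predict walkability scores for all nodes to disk
#'
#' Loads the trained model (from `cfg$model_file` or the out-dir default),
#' predicts a clipped 0-100 score for every node in the feature bundle and
#' writes `predictions.csv` plus `predictions.geojson`.
#'
#' @param cfg an `alf_config`
#' @return invisibly, the named score vector
#' @export
run_predict <- function(cfg = alf_config()) {
  model <- readRDS(cfg$model_file %||% file.path(cfg$out_dir, "model.rds"))
  bundle <- load_bundle_cfg(cfg)
  X <- assemble_features(bundle, cfg$combo)
  scores <- predict_scores(model, X)
  write.csv(data.frame(node_id = names(scores), alf_score = unname(scores)),
            file.path(cfg$out_dir, "predictions.csv"), row.names = FALSE)
  net <- load_network_cfg(cfg)
  nodes <- net$nodes[net$nodes$node_id %in% names(scores), , drop = FALSE]
  write_scores_geojson(nodes, scores,
                       file.path(cfg$out_dir, "predictions.geojson"))
  invisible(scores)
}

#' Evaluate a trained model on the labelled nodes to disk
#'
#' @param cfg an `alf_config`
#' @return invisibly, the `eval_report`
#' @export
run_evaluate <- function(cfg = alf_config()) {
  model <- readRDS(cfg$model_file %||% file.path(cfg$out_dir, "model.rds"))
  bundle <- load_bundle_cfg(cfg)
  y <- load_labels_cfg(cfg, bundle)
  keep <- rownames(bundle$poi) %in% names(y)
  X <- assemble_features(
    feature_bundle(bundle$poi[keep, , drop = FALSE],
                   bundle$network[keep, , drop = FALSE],
                   bundle$embedding[keep, , drop = FALSE]), cfg$combo)
  report <- evaluate_model(model, X, y[rownames(X)])
  jsonlite::write_json(unclass(report), file.path(cfg$out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
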