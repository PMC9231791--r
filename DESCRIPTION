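Package: alfscore
Title: Network-Based Walkability Scores from Crowd-Sourced Relative Rankings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building point-level walkability scores on road
    networks. Aggregates crowd-sourced relative rankings of small groups of
    road locations into one global walkability ordering with the GLEPO
    algorithm (anchor detection, randomized insertion, geographic virtual
    links, multi-iteration averaging), derives node features from the road
    network (eight centrality measures, distance-band point-of-interest
    indicators, random-walk node embeddings), and trains regression models
    that predict a 0-100 walkability score for any road node. Includes a
    synthetic-city generator so the full pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    geosphere,
    jsonlite,
    xml2,
    yaml,
    randomForest,
    e1071,
    rpart,
    xgboost,
    glmnet,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
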