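#' Bundle the three node-feature blocks
#'
#' Validates that the POI, network-centrality and embedding blocks share one
#' node ordering and packs them for [assemble_features()]. With the package
#' defaults the blocks contribute 530 + 8 + 128 = 666 columns.
#'
#' @param poi POI feature matrix from [extract_poi_features()].
#' @param network centrality table from [compute_centralities()].
#' @param embedding embedding matrix from [embed_nodes()].
#' @return object of class `feature_bundle`
#' @export
feature_bundle <- function(poi, network, embedding) {
  blocks <- list(poi = poi, network = network, embedding = embedding)
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    class(b) <- "matrix"
    b
  })
  ids <- rownames(blocks$poi)
  if (is.null(ids)) stopf("feature blocks need node-id rownames")
  for (nm in names(blocks)) {
    if (!identical(rownames(blocks[[nm]]), ids))
      stopf("node ids of block '%s' do not match the POI block", nm)
    if (any(!is.finite(blocks[[nm]])))
      stopf("block '%s' contains non-finite values", nm)
  }
  structure(blocks, class = "feature_bundle")
}

#' Assemble a feature matrix for a named combination
#'
#' Column-concatenates the requested blocks in the stable order
#' poi, network, embedding.
#'
#' @param bundle a `feature_bundle`
#' @param combo one of `"poi"`, `"network"`, `"embedding"`,
#'   `"poi+network"`, `"poi+embedding"`, `"network+embedding"`, `"all"`.
#' @return numeric matrix (nodes x features)
#' @export
assemble_features <- function(bundle, combo = "all") {
  stopifnot(inherits(bundle, "feature_bundle"))
  combos <- list(
    poi = "poi", network = "network", embedding = "embedding",
    `poi+network` = c("poi", "network"),
    `poi+embedding` = c("poi", "embedding"),
    `network+embedding` = c("network", "embedding"),
    all = c("poi", "network", "embedding"))
  if (!combo %in% names(combos))
    stopf("unknown combo '%s'; use one of: %s", combo,
          paste(names(combos), collapse = ", "))
  do.call(cbind, unname(bundle[combos[[combo]]]))
}

#' Feature combinations
#' @return character vector of the supported combination names
#' @export
feature_combos <- function() {
  c("poi", "network", "embedding", "poi+network", "poi+embedding",
    "network+embedding", "all")
}

#' One-hot encode categorical columns
#'
#' Each declared categorical column becomes one 0/1 indicator column per
#' observed level; within an encoded block every row sums to 1. Numeric
#' columns pass through unchanged.
#'
#' @param df data.frame with numeric and/or categorical columns.
#' @param categorical names of columns to encode; defaults to all factor /
#'   character columns.
#' @param levels optional named list fixing the level sets (for encoding
#'   new data with a training-time layout).
#' @param strict error on categories absent from `levels` (default); if
#'   `FALSE`, unseen categories produce an all-zero row in that block.
#' @return numeric matrix
#' @export
one_hot <- function(df, categorical = NULL, levels = NULL, strict = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(categorical))
    categorical <- names(df)[vapply(df, function(x)
      is.character(x) || is.factor(x), logical(1))]
  out <- list()
  for (nm in names(df)) {
    x <- df[[nm]]
    if (nm %in% categorical) {
      x <- as.character(x)
      lev <- if (!is.null(levels[[nm]])) levels[[nm]] else sort(unique(x))
      unseen <- setdiff(unique(x), lev)
      if (length(unseen) && strict)
        stopf("column '%s' has categories not in the declared levels: %s",
              nm, paste(unseen, collapse = ", "))
      m <- outer(x, lev, "==") * 1L
      colnames(m) <- paste(nm, lev, sep = "=")
      out[[nm]] <- m
    } else {
      m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, nm))
      out[[nm]] <- m
    }
  }
  res <- do.call(cbind, out)
  rownames(res) <- rownames(df)
  res
}

#' Train/test split
#'
#' Seeded random shuffle into disjoint, exhaustive train and test sets.
#' The common presets are 0.9, 0.8, 0.7 and 0.6 train fractions.
#'
#' @param X feature matrix; @param y label vector (same length as rows).
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a list of `X`, `y`, `idx`
#' @export
split_data <- function(X, y, train_fraction = 0.8, seed = 1L) {
  n <- nrow(X)
  if (length(y) != n) stopf("X and y disagree on the number of rows")
  if (n < 2L) stopf("need at least 2 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
  tr <- sort(idx[seq_len(n_train)])
  te <- sort(idx[(n_train + 1L):n])
  list(train = list(X = X[tr, , drop = FALSE], y = y[tr], idx = tr),
       test = list(X = X[te, , drop = FALSE], y = y[te], idx = te))
}

#' Supported regression techniques
#' @return character vector of technique names
#' @export
model_techniques <- function() {
  c("random_forest", "linear_regression", "decision_tree", "svr",
    "gradient_boosting", "mlp", "polynomial", "lasso_cv")
}

#' Train a walkability regressor
#'
#' Fits one of the supported regression techniques to a node-feature matrix
#' and 0-100 walkability labels. Defaults: random forest with 100 trees and
#' no depth cap; SVR with an RBF kernel, cost 1 and epsilon 0.2; gradient
#' boosting with depth 10, 100 rounds and learning rate 0.1; decision tree
#' with CART's exhaustive (best-split) search; MLP as a dense
#' single-hidden-layer network with linear output trained on standardized
#' features; polynomial as degree-2 (square-augmented) linear regression;
#' lasso with internal cross-validated penalty.
#'
#' @param technique one of [model_techniques()].
#' @param X numeric feature matrix (no missing values).
#' @param y numeric labels on the 0-100 scale.
#' @param hyperparams named list overriding technique defaults.
#' @param seed integer seed for the stochastic techniques.
#' @return object of class `alf_model`
#' @export
train_walkability <- function(technique, X, y, hyperparams = list(),
                              seed = 1L) {
  if (!technique %in% model_techniques())
    stopf("unknown technique '%s'; supported: %s", technique,
          paste(model_techniques(), collapse = ", "))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("X and y disagree on the number of rows")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stopf("missing or non-finite values are not allowed; impute or drop first")
  set.seed(as.integer(seed))
  hp <- hyperparams
  colnames(X) <- paste0("f", seq_len(ncol(X)))  # syntactic, collision-free

  fit <- switch(technique,
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = hp$ntree %||% 100L),
    linear_regression = {
      df <- data.frame(y = y, X, check.names = FALSE)
      suppressWarnings(lm(y ~ ., data = df))
    },
    decision_tree = {
      df <- data.frame(y = y, X, check.names = FALSE)
      rpart::rpart(y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = hp$maxdepth %||% 30L,
                     cp = hp$cp %||% 0.001, xval = 0))
    },
    svr = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = hp$kernel %||% "radial",
                     cost = hp$cost %||% 1,
                     epsilon = hp$epsilon %||% 0.2,
                     shrinking = TRUE, scale = ncol(X) > 0),
    gradient_boosting = xgboost::xgboost(
      x = X, y = y, nrounds = hp$nrounds %||% 100L,
      max_depth = hp$max_depth %||% 10L,
      learning_rate = hp$learning_rate %||% 0.1,
      objective = "reg:squarederror", nthreads = 1L, verbosity = 0),
    mlp = {
      ctr <- apply(X, 2, mean); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
      Z <- scale(X, center = ctr, scale = scl)
      size <- hp$size %||% 8L
      nn <- nnet::nnet(x = Z, y = y / 100, size = size, linout = TRUE,
                       decay = hp$decay %||% 1e-3,
                       maxit = hp$maxit %||% 400L,
                       MaxNWts = (ncol(X) + 2L) * size + size + 10L,
                       trace = FALSE)
      list(net = nn, center = ctr, scale = scl)
    },
    polynomial = {
      Xp <- cbind(X, X^2)
      colnames(Xp) <- c(colnames(X), paste0(colnames(X), "_sq"))
      df <- data.frame(y = y, Xp, check.names = FALSE)
      suppressWarnings(lm(y ~ ., data = df))
    },
    lasso_cv = glmnet::cv.glmnet(x = X, y = y,
                                 nfolds = hp$nfolds %||% 5L))

  structure(list(technique = technique, fit = fit, n_features = ncol(X),
                 hyperparams = hp, seed = seed),
            class = "alf_model")
}

#' @export
print.alf_model <- function(x, ...) {
  cat(sprintf("<alf_model> technique=%s, %d features\n",
              x$technique, x$n_features))
  invisible(x)
}

# raw (unclipped) predictions from a fitted model
predict_raw <- function(model, X) {
  stopifnot(inherits(model, "alf_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stopf("model expects %d feature columns, got %d", model$n_features, ncol(X))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  # linear fits are applied directly so rank-deficient (aliased) fits
  # predict like their training fitted values instead of tripping
  # predict.lm's estimability check
  apply_lm <- function(fit, M) {
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
    as.numeric(beta[1] + M %*% beta[-1])
  }
  out <- switch(model$technique,
    random_forest = predict(model$fit, X),
    linear_regression = apply_lm(model$fit, X),
    decision_tree = predict(model$fit, data.frame(X, check.names = FALSE)),
    svr = predict(model$fit, X),
    gradient_boosting = predict(model$fit, X),
    mlp = {
      Z <- scale(X, center = model$fit$center, scale = model$fit$scale)
      as.numeric(predict(model$fit$net, Z)) * 100
    },
    polynomial = {
      Xp <- cbind(X, X^2)
      colnames(Xp) <- c(colnames(X), paste0(colnames(X), "_sq"))
      apply_lm(model$fit, Xp)
    },
    lasso_cv = as.numeric(predict(model$fit, newx = X, s = "lambda.min")))
  as.numeric(out)
}

#' Predict walkability scores
#'
#' Predictions are clipped to the 0-100 score scale.
#'
#' @param model an `alf_model`
#' @param X feature matrix with the training column layout.
#' @return numeric vector of scores in \[0, 100\], named by rownames of `X`
#' @export
predict_scores <- function(model, X) {
  out <- clamp(predict_raw(model, X), 0, 100)
  names(out) <- rownames(X)
  out
}

#' Evaluate a model on held-out data
#'
#' MAE = mean |y - yhat|, RMSE = sqrt(mean (y - yhat)^2), and accuracy
#' defined on the 0-100 label scale as 100 - MAE (reported alongside the
#' raw errors, never instead of them).
#'
#' @param model an `alf_model`
#' @param X_test,y_test held-out features and labels.
#' @return object of class `eval_report`: list with `technique`, `mae`,
#'   `rmse`, `accuracy_pct`, `n_test`
#' @export
evaluate_model <- function(model, X_test, y_test) {
  if (!length(y_test)) stopf("empty test set")
  pred <- predict_scores(model, X_test)
  err <- y_test - pred
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  structure(list(technique = model$technique, mae = mae, rmse = rmse,
                 accuracy_pct = 100 - mae, n_test = length(y_test)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: MAE %.3f | RMSE %.3f | accuracy %.2f%% (n=%d)\n",
              x$technique, x$mae, x$rmse, x$accuracy_pct, x$n_test))
  invisible(x)
}

#' K-fold cross validation
#'
#' Seeded fold assignment; every row appears in exactly one test fold.
#'
#' @param technique one of [model_techniques()].
#' @param X,y features and labels.
#' @param k number of folds (2 <= k <= n).
#' @param hyperparams passed to [train_walkability()].
#' @param seed integer seed.
#' @return list with `folds` (list of `eval_report`) and `summary`
#'   (list: `mean_mae`, `sd_mae`, `mean_rmse`, `mean_accuracy_pct`)
#' @export
kfold_cv <- function(technique, X, y, k = 5L, hyperparams = list(), seed = 1L) {
  n <- nrow(X)
  if (k < 2L || k > n) stopf("k must satisfy 2 <= k <= n (= %d)", n)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  reports <- lapply(seq_len(k), function(f) {
    te <- which(fold == f); tr <- which(fold != f)
    m <- train_walkability(technique, X[tr, , drop = FALSE], y[tr],
                           hyperparams, seed = derive_seed(seed, f))
    evaluate_model(m, X[te, , drop = FALSE], y[te])
  })
  maes <- vapply(reports, `[[`, numeric(1), "mae")
  rmses <- vapply(reports, `[[`, numeric(1), "rmse")
  list(folds = reports,
       summary = list(mean_mae = mean(maes), sd_mae = sd(maes),
                      mean_rmse = mean(rmses),
                      mean_accuracy_pct = 100 - mean(maes)))
}

#' Technique-by-combination evaluation grid
#'
#' Trains and evaluates every requested technique on every requested
#' feature combination under one train/test split, producing the standard
#' grid report (rows = techniques, one accuracy column per combination).
#'
#' @param bundle a `feature_bundle`
#' @param y labels aligned with the bundle's node order.
#' @param techniques techniques to run (default: the six headline ones).
#' @param combos feature combinations (default: all seven).
#' @param train_fraction,seed split parameters.
#' @param hyperparams optional named list of per-technique hyperparameter
#'   lists.
#' @return data.frame of accuracies (plus MAE/RMSE in long attribute
#'   `details`)
#' @export
evaluation_grid <- function(bundle, y,
                            techniques = c("random_forest", "linear_regression",
                                           "svr", "gradient_boosting",
                                           "decision_tree", "mlp"),
                            combos = feature_combos(),
                            train_fraction = 0.8, seed = 1L,
                            hyperparams = list()) {
  stopifnot(inherits(bundle, "feature_bundle"))
  details <- list()
  acc <- matrix(NA_real_, nrow = length(techniques), ncol = length(combos),
                dimnames = list(techniques, combos))
  for (cb in combos) {
    X <- assemble_features(bundle, cb)
    sp <- split_data(X, y, train_fraction, seed = seed)
    for (tq in techniques) {
      m <- train_walkability(tq, sp$train$X, sp$train$y,
                             hyperparams[[tq]] %||% list(),
                             seed = derive_seed(seed, match(tq, techniques)))
      r <- evaluate_model(m, sp$test$X, sp$test$y)
      acc[tq, cb] <- r$accuracy_pct
      details[[paste(tq, cb, sep = "|")]] <-
        data.frame(technique = tq, combo = cb, mae = r$mae, rmse = r$rmse,
                   accuracy_pct = r$accuracy_pct, stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(technique = rownames(acc), acc, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "details") <- do.call(rbind, c(details, list(make.row.names = FALSE)))
  out
}
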