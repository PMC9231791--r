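make_small_bundle <- function(nn = 40, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", 1:nn)
  poi <- matrix(rbinom(nn * 6, 1, 0.5), nn, 6,
                dimnames = list(ids, paste0("k@", 1:6)))
  network <- matrix(runif(nn * 8), nn, 8,
                    dimnames = list(ids, paste0("c", 1:8)))
  emb <- matrix(rnorm(nn * 4), nn, 4, dimnames = list(ids, paste0("e", 1:4)))
  feature_bundle(poi, network, emb)
}

test_that("feature assembly concatenates blocks in stable order", {
  b <- make_small_bundle()
  expect_equal(ncol(assemble_features(b, "poi")), 6L)
  expect_equal(ncol(assemble_features(b, "network")), 8L)
  expect_equal(ncol(assemble_features(b, "embedding")), 4L)
  expect_equal(ncol(assemble_features(b, "poi+network")), 14L)
  expect_equal(ncol(assemble_features(b, "network+embedding")), 12L)
  all3 <- assemble_features(b, "all")
  expect_equal(ncol(all3), 18L)
  expect_equal(all3[, 1:6], b$poi, ignore_attr = TRUE)
  expect_equal(all3[, 15:18], b$embedding, ignore_attr = TRUE)
  expect_error(assemble_features(b, "poi+poi"), "unknown combo")
  # misaligned node ids are rejected at bundle time
  bad <- b$poi; rownames(bad) <- rev(rownames(bad))
  expect_error(feature_bundle(bad, b$network, b$embedding), "node ids")
})

test_that("one-hot encoding partitions each categorical column", {
  df <- data.frame(size = c("s", "m", "l", "m"), x = c(1, 2, 3, 4),
                   stringsAsFactors = FALSE)
  m <- one_hot(df)
  expect_equal(ncol(m), 4L)            # 3 levels + 1 numeric
  expect_equal(unname(rowSums(m[, paste0("size=", c("l", "m", "s"))])),
               rep(1, 4))
  expect_equal(m[, "x"], df$x, ignore_attr = TRUE)
  # numeric-only input passes through unchanged
  num <- data.frame(a = 1:3, b = 4:6)
  expect_equal(one_hot(num), as.matrix(num), ignore_attr = TRUE)
  # unseen categories: strict errors, lenient yields an all-zero block row
  expect_error(one_hot(df, levels = list(size = c("s", "m"))), "categories")
  m2 <- one_hot(df, levels = list(size = c("s", "m")), strict = FALSE)
  expect_equal(unname(rowSums(m2[, paste0("size=", c("s", "m"))])),
               c(1, 1, 0, 1))
})

test_that("train/test split is seeded, disjoint and exhaustive", {
  X <- matrix(rnorm(200), 100, 2)
  y <- rnorm(100)
  sp <- split_data(X, y, 0.8, seed = 4)
  expect_equal(nrow(sp$train$X), 80L)
  expect_equal(nrow(sp$test$X), 20L)
  expect_equal(sort(c(sp$train$idx, sp$test$idx)), 1:100)
  expect_length(intersect(sp$train$idx, sp$test$idx), 0L)
  sp2 <- split_data(X, y, 0.8, seed = 4)
  expect_identical(sp$train$idx, sp2$train$idx)
  for (f in c(0.9, 0.7, 0.6)) {
    spf <- split_data(X, y, f, seed = 1)
    expect_equal(nrow(spf$train$X), round(100 * f))
  }
  expect_error(split_data(X, y, 1.2), "train_fraction")
  expect_error(split_data(X[1, , drop = FALSE], y[1]), "2 rows")
})

test_that("exact-linear labels are recovered by linear regression", {
  set.seed(2)
  X <- matrix(runif(50 * 5, 0, 10), 50, 5)
  y <- 3 + 2 * X[, 1] - 0.5 * X[, 4]
  sp <- split_data(X, y, 0.8, seed = 1)
  m <- train_walkability("linear_regression", sp$train$X, sp$train$y)
  pred <- alfscore:::predict_raw(m, sp$test$X)
  expect_lt(mean(abs(pred - sp$test$y)), 1e-6)
})

test_that("random forest memorizes a feature-copy label", {
  set.seed(3)
  X <- matrix(runif(200, 0, 100), 200, 1)
  y <- X[, 1]
  m <- train_walkability("random_forest", X, y, seed = 1)
  expect_lt(mean(abs(predict_scores(m, X) - y)), 1.0)
})

test_that("every technique trains, predicts in range, and beats the mean baseline", {
  set.seed(8)
  n <- 120
  X <- matrix(runif(n * 4, 0, 10), n, 4)
  y <- pmin(pmax(20 + 5 * X[, 1] + 2 * X[, 2] + rnorm(n, 0, 2), 0), 100)
  sp <- split_data(X, y, 0.8, seed = 2)
  base_mae <- mean(abs(sp$test$y - mean(sp$train$y)))
  for (tq in model_techniques()) {
    m <- train_walkability(tq, sp$train$X, sp$train$y, seed = 5)
    p <- predict_scores(m, sp$test$X)
    expect_true(all(p >= 0 & p <= 100), info = tq)
    r <- evaluate_model(m, sp$test$X, sp$test$y)
    expect_gte(r$rmse, r$mae)
    expect_lt(r$mae, base_mae)
  }
  expect_error(train_walkability("neural_turing_machine", X, y), "supported")
  expect_error(train_walkability("svr", X, c(y[-1], NA)), "missing")
})

test_that("evaluation metrics match closed forms", {
  set.seed(4)
  X <- matrix(runif(60, 10, 90), 30, 2)
  y <- 0.5 * X[, 1] + 0.2 * X[, 2]          # mid-range, clipping inactive
  m <- train_walkability("linear_regression", X, y)
  perfect <- evaluate_model(m, X, y)
  expect_equal(perfect$mae, 0, tolerance = 1e-8)
  expect_equal(perfect$rmse, 0, tolerance = 1e-8)
  expect_equal(perfect$accuracy_pct, 100, tolerance = 1e-8)
  shifted <- evaluate_model(m, X, y + 5)
  expect_equal(shifted$mae, 5, tolerance = 1e-8)
  expect_equal(shifted$rmse, 5, tolerance = 1e-8)
  expect_equal(shifted$accuracy_pct, 95, tolerance = 1e-8)
  y3 <- y[1:3] + c(0, 0, 6)
  r3 <- evaluate_model(m, X[1:3, , drop = FALSE], y3)
  expect_equal(r3$mae, 2, tolerance = 1e-8)
  expect_equal(r3$rmse, sqrt(12), tolerance = 1e-8)
  expect_error(evaluate_model(m, X[0, , drop = FALSE], numeric(0)), "empty")
  expect_error(predict_scores(m, X[, 1, drop = FALSE]), "columns")
})

test_that("k-fold cross validation partitions the rows", {
  set.seed(6)
  X <- matrix(runif(100 * 3), 100, 3)
  y <- 50 + 20 * X[, 1]
  cv <- kfold_cv("decision_tree", X, y, k = 5, seed = 3)
  expect_length(cv$folds, 5L)
  ns <- vapply(cv$folds, `[[`, numeric(1), "n_test")
  expect_equal(unname(ns), rep(20, 5))
  expect_true(is.finite(cv$summary$mean_mae))
  # leave-one-out on a small subset
  loo <- kfold_cv("linear_regression", X[1:8, ], y[1:8], k = 8, seed = 1)
  expect_length(loo$folds, 8L)
  expect_error(kfold_cv("decision_tree", X, y, k = 101), "k must")
})

test_that("random forest beats linear regression on non-linear labels", {
  deltas <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 150
    X <- matrix(runif(n * 4, 0, 10), n, 4)
    y <- pmin(pmax(50 + 25 * sin(X[, 1]) + 0.8 * (X[, 2] - 5)^2 +
                     rnorm(n, 0, 3), 0), 100)
    sp <- split_data(X, y, 0.8, seed = s)
    rf <- evaluate_model(train_walkability("random_forest", sp$train$X,
                                           sp$train$y, seed = s),
                         sp$test$X, sp$test$y)
    lin <- evaluate_model(train_walkability("linear_regression", sp$train$X,
                                            sp$train$y),
                          sp$test$X, sp$test$y)
    lin$mae - rf$mae
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("the technique-by-combination grid has the report shape", {
  b <- make_small_bundle(nn = 60, seed = 9)
  set.seed(9)
  y <- pmin(pmax(10 * rowSums(b$network[, 1:2]) + 30 * b$poi[, 1] +
                   rnorm(60, 0, 2) + 20, 0), 100)
  grid <- evaluation_grid(b, y,
                          techniques = c("decision_tree", "linear_regression"),
                          combos = c("poi", "network+embedding", "all"),
                          seed = 2)
  expect_equal(dim(grid), c(2L, 4L))      # technique column + 3 combos
  expect_equal(grid$technique, c("decision_tree", "linear_regression"))
  expect_true(all(is.finite(as.matrix(grid[, -1]))))
  det <- attr(grid, "details")
  expect_equal(nrow(det), 6L)
  expect_true(all(det$rmse >= det$mae))
})
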