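# Learner registry, training, prediction alignment, cross-validation and
# grid search. Small problem sizes keep each learner's fit fast.

quick_params <- list(
  mlr = NULL, knn = list(k = 3),
  rf = list(num.trees = 100),
  svm = NULL,
  ann = list(size = 4, maxit = 150),
  adaboost = list(n_estimators = 15, max_depth = 2),
  xgboost = list(nrounds = 40)
)

toy_xy <- function(n = 40, seed = 61, noise = 0.2) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  list(X = X, y = 2 * X[, "x1"] - X[, "x2"] + rnorm(n, 0, noise))
}

test_that("linear regression reproduces an exactly linear signal", {
  set.seed(62)
  X <- cbind(x1 = rnorm(12))
  y <- 2 * X[, "x1"] + 1
  m <- train_model(learner_spec("mlr"), X, y)
  expect_equal(predict(m, X), y, tolerance = 1e-6)
})

test_that("1-nearest-neighbour predicts training targets exactly", {
  d <- toy_xy()
  m <- train_model(learner_spec("knn"), d$X, d$y, params = list(k = 1))
  expect_equal(predict(m, d$X), d$y, tolerance = 1e-12)
})

test_that("every learner is deterministic under a fixed seed", {
  d <- toy_xy()
  for (ln in names(quick_params)) {
    m1 <- train_model(learner_spec(ln), d$X, d$y,
                      params = quick_params[[ln]], seed = 63)
    m2 <- train_model(learner_spec(ln), d$X, d$y,
                      params = quick_params[[ln]], seed = 63)
    expect_identical(predict(m1, d$X), predict(m2, d$X), label = ln)
  }
})

test_that("the lightgbm learner trains, predicts deterministically, persists", {
  d <- toy_xy(60)
  m1 <- train_model(learner_spec("lightgbm"), d$X, d$y,
                    params = list(n_estimators = 30), seed = 64)
  p1 <- predict(m1, d$X)
  expect_length(p1, 60L)
  expect_true(all(is.finite(p1)))
  expect_gt(r_squared(d$y, p1), 0.5)
  path <- tempfile(fileext = ".rds")
  save_model(m1, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, d$X), p1)
})

test_that("prediction aligns columns by name and reports missing features", {
  d <- toy_xy()
  m <- train_model(learner_spec("mlr"), d$X, d$y)
  p0 <- predict(m, d$X)
  # permuted column order: identical predictions
  expect_equal(predict(m, d$X[, c("x3", "x1", "x2")]), p0)
  # extra irrelevant columns: ignored
  extra <- cbind(d$X, junk = rnorm(nrow(d$X)))
  expect_equal(predict(m, extra), p0)
  # missing column: named schema error listing the name
  expect_error(predict(m, d$X[, c("x1", "x2")]), "x3",
               class = "bbbqsar_schema_error")
})

test_that("unknown learners and degenerate inputs raise named errors", {
  d <- toy_xy()
  expect_error(learner_spec("deeplearn"), class = "bbbqsar_schema_error")
  Xbad <- d$X; Xbad[1, 1] <- NA
  expect_error(train_model(learner_spec("mlr"), Xbad, d$y),
               class = "bbbqsar_schema_error")
  expect_error(train_model(learner_spec("mlr"), d$X[1:5, ], d$y[1:5]),
               class = "bbbqsar_schema_error")
})

test_that("cross-validation folds partition the rows disjointly", {
  d <- toy_xy(53)
  cv <- cross_validate(learner_spec("mlr"), d$X, d$y, k = 7, seed = 65)
  all_idx <- unname(sort(unlist(cv$folds)))
  expect_equal(all_idx, seq_len(53))
  expect_equal(length(unique(unlist(cv$folds))), 53L)
  expect_equal(cv$mean_r2, mean(cv$per_fold$r2))
  expect_equal(cv$mean_mse, mean(cv$per_fold$mse))
  expect_error(cross_validate(learner_spec("mlr"), d$X, d$y, k = 1),
               class = "bbbqsar_schema_error")
  expect_error(cross_validate(learner_spec("mlr"), d$X, d$y, k = 99),
               class = "bbbqsar_schema_error")
})

test_that("noise-free linear data yields CV R2 of exactly 1 under MLR", {
  d <- toy_xy(60, noise = 0)
  cv <- cross_validate(learner_spec("mlr"), d$X, d$y, k = 10, seed = 66)
  expect_equal(cv$mean_r2, 1.0, tolerance = 1e-9)
})

test_that("tree ensembles beat linear regression on a nonlinear signal", {
  wins_xgb <- 0; wins_rf <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 250
    X <- cbind(x1 = runif(n, -3, 3), x2 = runif(n, -2, 2))
    y <- sin(X[, "x1"]) + X[, "x2"]^2 + rnorm(n, 0, 0.1)
    r2 <- function(ln, p) cross_validate(learner_spec(ln), X, y, k = 5,
                                         seed = s, params = p)$mean_r2
    base <- r2("mlr", NULL)
    if (r2("xgboost", list(nrounds = 100)) > base) wins_xgb <- wins_xgb + 1
    if (r2("rf", list(num.trees = 150)) > base) wins_rf <- wins_rf + 1
  }
  expect_equal(wins_xgb, 5L)
  expect_equal(wins_rf, 5L)
})

test_that("grid search is exhaustive, deterministic, and never beaten on its folds", {
  set.seed(71)
  n <- 150
  X <- cbind(x1 = runif(n, -3, 3), x2 = runif(n, -2, 2))
  y <- sin(X[, "x1"]) + X[, "x2"]^2 + rnorm(n, 0, 0.1)
  spec <- learner_spec("xgboost",
                       param_grid = list(eta = c(0.001, 0.3),
                                         nrounds = c(1, 100)))
  gs <- grid_search(spec, X, y, k = 4, seed = 72)
  # the degenerate one-round low-rate setting must lose
  expect_equal(gs$best_params$eta, 0.3)
  expect_equal(gs$best_params$nrounds, 100)
  expect_equal(max(gs$results$mean_r2), gs$best_cv$mean_r2)
  gs2 <- grid_search(spec, X, y, k = 4, seed = 72)
  expect_identical(gs$best_params, gs2$best_params)
  # single-point grid returns that point
  one <- grid_search(learner_spec("xgboost",
                                  param_grid = list(nrounds = 30)),
                     X, y, k = 4, seed = 72)
  expect_equal(one$best_params$nrounds, 30)
  expect_error(grid_search(learner_spec("mlr"), X, y, k = 4),
               class = "bbbqsar_schema_error")
})

test_that("model archives refuse a format-version mismatch", {
  d <- toy_xy()
  m <- train_model(learner_spec("mlr"), d$X, d$y)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  stale <- readRDS(path)
  stale$format_version <- 99L
  saveRDS(stale, path)
  expect_error(load_model(path), class = "bbbqsar_schema_error")
  expect_error(load_model(tempfile()), class = "bbbqsar_io_error")
})
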