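# Learner backends. Each backend is a pair of functions:
#   fit(X, y, params, seed) -> opaque fit object
#   predict(fit, X) -> numeric vector
# X is a fully finite numeric matrix (already standardized by the harness).
# Every backend is deterministic for a fixed seed and num_threads = 1.

# ---- multiple linear regression --------------------------------------------
.fit_mlr <- function(X, y, params, seed) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  coefs <- fit$coefficients
  coefs[!is.finite(coefs)] <- 0  # exactly collinear columns contribute 0
  list(coefficients = coefs)
}
.predict_mlr <- function(fit, X) {
  as.numeric(cbind(1, X) %*% fit$coefficients)
}

# ---- k-nearest neighbours ---------------------------------------------------
.fit_knn <- function(X, y, params, seed) {
  k <- params$k %||% 5
  caret::knnreg(as.data.frame(X), y, k = min(k, nrow(X)))
}
.predict_knn <- function(fit, X) {
  as.numeric(stats::predict(fit, as.data.frame(X)))
}

# ---- random forest ----------------------------------------------------------
.fit_rf <- function(X, y, params, seed) {
  d <- as.data.frame(X)
  d$.y <- y
  ranger::ranger(dependent.variable.name = ".y", data = d,
                 num.trees = params$num.trees %||% 500,
                 min.node.size = params$min.node.size %||% 5,
                 mtry = params$mtry %||% max(1L, floor(ncol(X) / 3)),
                 seed = seed, num.threads = 1)
}
.predict_rf <- function(fit, X) {
  as.numeric(stats::predict(fit, data = as.data.frame(X),
                            num.threads = 1)$predictions)
}

# ---- support vector regression (RBF) ---------------------------------------
.fit_svm <- function(X, y, params, seed) {
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = params$cost %||% 1,
             gamma = params$gamma %||% (1 / ncol(X)),
             epsilon = params$epsilon %||% 0.1, scale = FALSE)
}
.predict_svm <- function(fit, X) as.numeric(stats::predict(fit, X))

# ---- single-hidden-layer neural network ------------------------------------
.fit_ann <- function(X, y, params, seed) {
  size <- params$size %||% min(64, ncol(X))
  set.seed(seed)
  # center the response so the linear output unit starts near the data scale
  mu <- mean(y); s <- stats::sd(y); if (!is.finite(s) || s == 0) s <- 1
  fit <- nnet::nnet(x = X, y = (y - mu) / s, size = size,
                    decay = params$decay %||% 0.01,
                    maxit = params$maxit %||% 500,
                    linout = TRUE, trace = FALSE, MaxNWts = 100000)
  list(net = fit, mu = mu, s = s)
}
.predict_ann <- function(fit, X) {
  as.numeric(stats::predict(fit$net, X)) * fit$s + fit$mu
}

# ---- gradient boosting (XGBoost) -------------------------------------------
.fit_xgboost <- function(X, y, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = list(eta = params$eta %||% 0.1,
                                   max_depth = params$max_depth %||% 4,
                                   min_child_weight = params$min_child_weight %||% 1,
                                   subsample = params$subsample %||% 1,
                                   objective = "reg:squarederror",
                                   nthread = 1, seed = seed),
                     data = dtrain,
                     nrounds = params$nrounds %||% 200,
                     verbose = 0)
}
.predict_xgboost <- function(fit, X) {
  as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
}

# ---- AdaBoost.R2 over regression trees -------------------------------------
# Drucker's AdaBoost for regression with linear loss: reweight training
# points by relative absolute error, stop early when the weighted loss
# reaches 0.5, and predict with the weighted median of the stage trees.
.fit_adaboost <- function(X, y, params, seed) {
  n_estimators <- params$n_estimators %||% 50
  max_depth <- params$max_depth %||% 3
  n <- nrow(X)
  set.seed(seed)
  w <- rep(1 / n, n)
  d <- as.data.frame(X)
  d$.y <- y
  trees <- list(); betas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 0, xval = 0,
                          minsplit = 5, minbucket = 2))
    pred <- stats::predict(fit, d)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) { trees[[m]] <- fit; betas[m] <- 1e-10; break }
    L <- err / emax
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) { if (m == 1L) { trees[[m]] <- fit; betas[m] <- 1 }; break }
    beta <- Lbar / (1 - Lbar)
    trees[[m]] <- fit; betas[m] <- beta
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  list(trees = trees, betas = betas)
}
.predict_adaboost <- function(fit, X) {
  d <- as.data.frame(X)
  preds <- vapply(fit$trees, function(tr) stats::predict(tr, d),
                  numeric(nrow(d)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(d))
  wts <- log(1 / pmax(fit$betas, 1e-300))
  # weighted median across stages, per observation
  apply_row <- function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1L]]
  }
  apply(preds, 1L, apply_row)
}

# ---- LightGBM via the Python backend ---------------------------------------
# No R LightGBM build is available here; the learner runs the LightGBM
# library through a small batch subprocess (inst/python/lightgbm_backend.py)
# with deterministic single-thread settings. The fitted model is the
# LightGBM text dump, carried inside the R model object.
.python_bin <- function() {
  p <- getOption("bbbqsar.python", Sys.which("python"))
  if (!nzchar(p))
    bbb_error("bbbqsar_unsupported_error",
              "no python interpreter found for the lightgbm learner")
  p
}

.lgbm_call <- function(mode, model_file, train_file = NULL, query_file = NULL,
                       params_file = NULL, pred_file = NULL) {
  script <- system.file("python", "lightgbm_backend.py", package = "bbbqsar")
  if (!nzchar(script))
    script <- file.path("inst", "python", "lightgbm_backend.py")
  args <- c(script, mode, "--model", model_file)
  if (!is.null(train_file)) args <- c(args, "--train", train_file)
  if (!is.null(query_file)) args <- c(args, "--query", query_file)
  if (!is.null(params_file)) args <- c(args, "--params", params_file)
  if (!is.null(pred_file)) args <- c(args, "--pred", pred_file)
  out <- suppressWarnings(system2(.python_bin(), args, stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    bbb_error("bbbqsar_internal_error",
              sprintf("lightgbm backend failed: %s",
                      paste(out, collapse = "\n")))
  invisible(out)
}

.fit_lightgbm <- function(X, y, params, seed) {
  td <- tempfile("lgbm_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  train_file <- file.path(td, "train.csv")
  model_file <- file.path(td, "model.txt")
  params_file <- file.path(td, "params.json")
  utils::write.csv(data.frame(X, check.names = FALSE, y = y), train_file,
                   row.names = FALSE)
  p <- list(learning_rate = params$learning_rate %||% 0.1,
            num_leaves = params$num_leaves %||% 31,
            n_estimators = params$n_estimators %||% 100,
            min_child_samples = params$min_child_samples %||% 5,
            seed = seed)
  jsonlite::write_json(p, params_file, auto_unbox = TRUE)
  .lgbm_call("fit", model_file, train_file = train_file,
             params_file = params_file)
  list(model_str = paste(readLines(model_file, warn = FALSE), collapse = "\n"),
       features = colnames(X))
}
.predict_lightgbm <- function(fit, X) {
  td <- tempfile("lgbm_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  model_file <- file.path(td, "model.txt")
  query_file <- file.path(td, "query.csv")
  pred_file <- file.path(td, "pred.csv")
  writeLines(fit$model_str, model_file)
  utils::write.csv(data.frame(X, check.names = FALSE), query_file,
                   row.names = FALSE)
  .lgbm_call("predict", model_file, query_file = query_file,
             pred_file = pred_file)
  as.numeric(readLines(pred_file, warn = FALSE))
}

# ---- registry ---------------------------------------------------------------
.LEARNERS <- list(
  lightgbm = list(fit = .fit_lightgbm, predict = .predict_lightgbm),
  rf       = list(fit = .fit_rf,       predict = .predict_rf),
  knn      = list(fit = .fit_knn,      predict = .predict_knn),
  mlr      = list(fit = .fit_mlr,      predict = .predict_mlr),
  svm      = list(fit = .fit_svm,      predict = .predict_svm),
  adaboost = list(fit = .fit_adaboost, predict = .predict_adaboost),
  xgboost  = list(fit = .fit_xgboost,  predict = .predict_xgboost),
  ann      = list(fit = .fit_ann,      predict = .predict_ann)
)

.default_fixed <- function(name) {
  switch(name,
    lightgbm = list(learning_rate = 0.1, num_leaves = 31, n_estimators = 100,
                    min_child_samples = 5),
    rf = list(num.trees = 500, min.node.size = 5),
    knn = list(k = 5),
    mlr = list(),
    svm = list(cost = 1, epsilon = 0.1),
    adaboost = list(n_estimators = 50, max_depth = 3),
    xgboost = list(eta = 0.1, max_depth = 4, nrounds = 200),
    ann = list(decay = 0.01, maxit = 500),
    bbb_error("bbbqsar_schema_error", sprintf("unknown learner: %s", name)))
}
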