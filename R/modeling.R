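# Uniform learner registry and cross-validation harness. Eight regression
# learners share one surface: LightGBM, random forest, k-nearest neighbours,
# multiple linear regression, support vector regression, AdaBoost.R2,
# XGBoost and a single-hidden-layer neural network. Features are
# standardized inside each CV fold by default (training-fold statistics
# only); `prescale = TRUE` reproduces the global pre-scaling protocol.

.LEARNER_NAMES <- c("lightgbm", "rf", "knn", "mlr", "svm", "adaboost",
                    "xgboost", "ann")
.MODEL_FORMAT_VERSION <- 1L

#' Describe a learner and its hyperparameter grid
#'
#' @param name One of `"lightgbm"`, `"rf"`, `"knn"`, `"mlr"`, `"svm"`,
#'   `"adaboost"`, `"xgboost"`, `"ann"`.
#' @param param_grid Named list of candidate value vectors for
#'   [grid_search()]; `NULL` uses the shipped default grid
#'   ([default_param_grid()]).
#' @param fixed_params Named list of hyperparameters merged over the
#'   learner's defaults for single fits.
#' @return Object of class `bbb_learner_spec`.
#' @export
learner_spec <- function(name, param_grid = NULL, fixed_params = list()) {
  if (!name %in% .LEARNER_NAMES)
    bbb_error("bbbqsar_schema_error",
              sprintf("unknown learner '%s' (choose from: %s)", name,
                      paste(.LEARNER_NAMES, collapse = ", ")))
  structure(list(name = name,
                 param_grid = param_grid %||% default_param_grid(name),
                 fixed_params = fixed_params),
            class = "bbb_learner_spec")
}

#' Default hyperparameter grids
#'
#' Reads the shipped grid configuration (`inst/config/default_grids.yaml`).
#' All grids are user-overridable through [learner_spec()].
#'
#' @param name Learner name.
#' @return Named list of candidate value vectors (may be empty, e.g. for
#'   plain linear regression).
#' @export
default_param_grid <- function(name) {
  path <- system.file("config", "default_grids.yaml", package = "bbbqsar")
  if (!nzchar(path)) path <- file.path("inst", "config", "default_grids.yaml")
  grids <- yaml::read_yaml(path)
  grids[[name]] %||% list()
}

.resolve_params <- function(spec, params) {
  p <- .default_fixed(spec$name)
  for (nm in names(spec$fixed_params)) p[[nm]] <- spec$fixed_params[[nm]]
  for (nm in names(params)) p[[nm]] <- params[[nm]]
  p
}

.check_xy <- function(X, y, min_rows = 10L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  if (!all(is.finite(X)) || !all(is.finite(y)))
    bbb_error("bbbqsar_schema_error", "non-finite values in training data")
  if (nrow(X) != length(y))
    bbb_error("bbbqsar_schema_error", "X rows and y length differ")
  if (nrow(X) < min_rows)
    bbb_error("bbbqsar_schema_error",
              sprintf("need at least %d training rows", min_rows))
  X
}

# Shuffled contiguous k-way split; the partition depends only on (n, k, seed).
.make_folds <- function(n, k, seed) {
  if (k < 2L || k > n)
    bbb_error("bbbqsar_schema_error",
              sprintf("k must be in [2, %d], got %s", n, k))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' Train a regression model on the full dataset
#'
#' Fits the learner on all rows after standardizing features (the scaler is
#' stored in the model and re-applied at prediction time). Deterministic
#' for a fixed seed.
#'
#' @param spec A [learner_spec()].
#' @param X Feature matrix (named columns, finite, >= 10 rows).
#' @param y Numeric logBB response.
#' @param params Named list of hyperparameters overriding the learner specification's fixed
#'   parameters and the learner defaults.
#' @param seed Integer seed.
#' @return Object of class `bbb_model` carrying the fitted state, the
#'   selected feature names, the scaler, and training metadata.
#' @export
train_model <- function(spec, X, y, params = NULL, seed = 42) {
  stopifnot(inherits(spec, "bbb_learner_spec"))
  X <- .check_xy(X, y)
  p <- .resolve_params(spec, params)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  backend <- .LEARNERS[[spec$name]]
  fit <- backend$fit(Xs, y, p, seed)
  structure(list(learner = spec$name, fit = fit,
                 features = scaler$names, scaler = scaler,
                 params = p, seed = seed, n_train = nrow(X),
                 format_version = .MODEL_FORMAT_VERSION,
                 package_version = as.character(utils::packageVersion("bbbqsar"))),
            class = "bbb_model")
}

#' @export
print.bbb_model <- function(x, ...) {
  cat(sprintf("<bbb_model> %s: %d features, %d training compounds (seed %d)\n",
              x$learner, length(x$features), x$n_train, x$seed))
  invisible(x)
}

#' Predict logBB for query compounds
#'
#' Columns are matched to the model's selected features by name, so column
#' order is irrelevant and extra columns are ignored; missing features raise
#' a schema error listing their names.
#'
#' @param object A `bbb_model`.
#' @param newdata Matrix or data.frame whose columns cover the model's
#'   features.
#' @param ... Unused.
#' @return Numeric vector of predicted logBB, one finite value per row.
#' @export
predict.bbb_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$features, colnames(newdata))
  if (length(missing_cols) > 0L)
    bbb_error("bbbqsar_schema_error",
              sprintf("query is missing required feature(s): %s",
                      paste(missing_cols, collapse = ", ")))
  Xs <- apply_scaler(newdata, object$scaler)
  pred <- .LEARNERS[[object$learner]]$predict(object$fit, Xs)
  if (!all(is.finite(pred)))
    bbb_error("bbbqsar_internal_error", "non-finite predictions produced")
  as.numeric(pred)
}

#' k-fold cross-validation of a learner
#'
#' Shuffled k-fold split derived from the seed alone. Per fold: fit the
#' scaler on the training part (unless `prescale`), train, predict the
#' held-out part, and record R-squared and MSE. The record keeps per-fold
#' values, their arithmetic means, the fold partition, and the out-of-fold
#' predictions.
#'
#' @param spec A [learner_spec()].
#' @param X Feature matrix; `y` the response.
#' @param y Numeric response vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle and learner fits.
#' @param params Hyperparameter overrides (see [train_model()]).
#' @param prescale Fit one scaler on all rows before splitting, reproducing
#'   protocols that standardize before cross-validation; the default
#'   (`FALSE`) refits the scaler inside each fold, which is leakage-free.
#' @return Object of class `bbb_cv`: list with `k`, `seed`, `folds`,
#'   `per_fold` (data.frame `fold`, `r2`, `mse`), `mean_r2`, `mean_mse`,
#'   `oof` (out-of-fold predictions in row order), `learner`, `params`.
#' @export
cross_validate <- function(spec, X, y, k = 10, seed = 42, params = NULL,
                           prescale = FALSE) {
  stopifnot(inherits(spec, "bbb_learner_spec"))
  X <- .check_xy(X, y, min_rows = 2L)
  p <- .resolve_params(spec, params)
  folds <- .make_folds(nrow(X), k, seed)
  backend <- .LEARNERS[[spec$name]]
  if (prescale) {
    sc_all <- fit_scaler(X)
    Xall <- apply_scaler(X, sc_all)
  }
  oof <- rep(NA_real_, nrow(X))
  per <- data.frame(fold = seq_len(k), r2 = NA_real_, mse = NA_real_)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    if (prescale) {
      Xtr <- Xall[train_idx, , drop = FALSE]
      Xte <- Xall[test_idx, , drop = FALSE]
    } else {
      sc <- fit_scaler(X[train_idx, , drop = FALSE])
      Xtr <- apply_scaler(X[train_idx, , drop = FALSE], sc)
      Xte <- apply_scaler(X[test_idx, , drop = FALSE], sc)
    }
    fit <- backend$fit(Xtr, y[train_idx], p, seed)
    pred <- backend$predict(fit, Xte)
    oof[test_idx] <- pred
    per$r2[i] <- tryCatch(r_squared(y[test_idx], pred),
                          error = function(e) NA_real_)
    per$mse[i] <- mse(y[test_idx], pred)
  }
  structure(list(k = k, seed = seed, folds = folds, per_fold = per,
                 mean_r2 = mean(per$r2, na.rm = TRUE),
                 mean_mse = mean(per$mse),
                 oof = oof, learner = spec$name, params = p),
            class = "bbb_cv")
}

#' @export
print.bbb_cv <- function(x, ...) {
  cat(sprintf("<bbb_cv> %s, %d-fold (seed %d): mean R2 %.4f, mean MSE %.4f\n",
              x$learner, x$k, x$seed, x$mean_r2, x$mean_mse))
  invisible(x)
}

#' Exhaustive hyperparameter grid search under cross-validation
#'
#' Evaluates every point of the Cartesian product of the specification's grid with
#' k-fold CV (all points share the same fold partition), picks the point
#' with the highest mean CV R-squared (ties: first in deterministic
#' enumeration order), and refits on all rows with the winning parameters.
#'
#' @param spec A [learner_spec()] with a non-empty `param_grid`.
#' @param X Feature matrix; `y` the response.
#' @param y Numeric response vector.
#' @param k Number of folds; `seed` the common fold/fit seed.
#' @param seed Integer seed.
#' @return List with `best_params`, `model` (refit on all data), `results`
#'   (one row per grid point with mean CV R-squared/MSE), and `best_cv`.
#' @export
grid_search <- function(spec, X, y, k = 10, seed = 42) {
  stopifnot(inherits(spec, "bbb_learner_spec"))
  grid <- spec$param_grid
  if (length(grid) == 0L)
    bbb_error("bbbqsar_schema_error",
              sprintf("empty parameter grid for learner '%s'", spec$name))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  results <- combos
  results$mean_r2 <- NA_real_
  results$mean_mse <- NA_real_
  cvs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- as.list(combos[i, , drop = FALSE])
    cv <- cross_validate(spec, X, y, k = k, seed = seed, params = p)
    cvs[[i]] <- cv
    results$mean_r2[i] <- cv$mean_r2
    results$mean_mse[i] <- cv$mean_mse
  }
  best <- which.max(results$mean_r2)  # first maximum wins ties
  best_params <- as.list(combos[best, , drop = FALSE])
  model <- train_model(spec, X, y, params = best_params, seed = seed)
  list(best_params = best_params, model = model, results = results,
       best_cv = cvs[[best]])
}

#' Save / load a trained model archive
#'
#' The archive carries the fitted state, feature names, scaler statistics
#' and training metadata. Loading refuses a format-version mismatch so
#' predictions stay reproducible across package revisions.
#'
#' @param model A `bbb_model`.
#' @param path Archive path.
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bbb_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    bbb_error("bbbqsar_io_error", sprintf("model file not found: %s", path))
  model <- readRDS(path)
  if (!inherits(model, "bbb_model") ||
      !identical(model$format_version, .MODEL_FORMAT_VERSION))
    bbb_error("bbbqsar_schema_error",
              "model archive version mismatch; retrain with this package version")
  model
}
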