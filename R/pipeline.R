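# End-to-end orchestration: curate -> featurize -> select -> train ->
# evaluate -> predict, driven by a single YAML (or R list) config, with
# per-stage logging, a JSON run manifest, and seeds everywhere randomness
# enters. Two runs with the same config produce identical outputs
# (manifest timings aside).

.pipeline_defaults <- function() {
  list(smiles_col = "smiles", logbb_col = "logbb", id_col = NULL,
       tanimoto_cutoff = 0.85,
       pcc_threshold = NULL,
       pcc_thresholds = seq(0.1, 0.9, by = 0.1),
       learner = "lightgbm", folds = 10, seed = 42,
       grid = NULL, params = NULL, prescale = FALSE,
       test = NULL, query = NULL, query_format = "csv",
       logbb_cutoff = -1.0, outdir = "bbbqsar_run")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run the full logBB modeling pipeline
#'
#' Executes, in order: dataset reading, Tanimoto deduplication (cutoff
#' 0.85), 2D descriptor computation and missing-value pruning, correlation
#' filtering (a fixed `pcc_threshold` skips the sweep; otherwise thresholds
#' 0.1-0.9 are swept and the best CV R-squared wins), model training
#' (grid search when a `grid` is configured), evaluation (cross-validation
#' always; an independent `test` file, screened against the training set at
#' the Tanimoto cutoff, when given), and prediction of an optional `query`
#' file with classification at logBB >= -1. Every stage logs its counts;
#' any failure aborts with the stage named.
#'
#' @param config Named list or path to a YAML file. Required key: `input`
#'   (training CSV with SMILES and logBB columns). Optional keys and their
#'   defaults: `smiles_col` "smiles", `logbb_col` "logbb", `id_col`,
#'   `tanimoto_cutoff` 0.85, `pcc_threshold` (NULL = sweep),
#'   `pcc_thresholds` 0.1-0.9, `learner` "lightgbm", `folds` 10, `seed` 42,
#'   `grid` (named list of candidate vectors), `params` (fixed
#'   hyperparameters), `prescale` FALSE, `test`, `query`, `query_format`,
#'   `logbb_cutoff` -1, `outdir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the trained `model`, `cv` record,
#'   `selection`, `evaluation`, file `paths`, and the `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$input))
    bbb_error("bbbqsar_schema_error", "config must name an 'input' dataset")
  cfg <- .pipeline_defaults()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  timings <- list()
  counts <- list()

  st <- .stage("read", read_dataset(cfg$input, "csv", cfg$smiles_col,
                                    cfg$logbb_col, cfg$id_col))
  ds <- st$value; timings$read <- st$elapsed
  counts$compounds_read <- nrow(ds) + nrow(attr(ds, "rejected"))
  counts$compounds_parsed <- nrow(ds)
  say("read: %d rows, %d parsed", counts$compounds_read, nrow(ds))

  st <- .stage("curate", deduplicate(ds, cfg$tanimoto_cutoff))
  dd <- st$value; timings$curate <- st$elapsed
  train_set <- dd$kept
  counts$compounds_kept <- nrow(train_set)
  counts$compounds_discarded <- nrow(ds) - nrow(train_set)
  say("curate: %d kept, %d discarded (Tanimoto > %.2f)",
      nrow(train_set), counts$compounds_discarded, cfg$tanimoto_cutoff)
  paths$kept <- file.path(cfg$outdir, "kept.csv")
  utils::write.csv(train_set, paths$kept, row.names = FALSE)
  paths$discards <- file.path(cfg$outdir, "discards.csv")
  utils::write.csv(dd$decisions[!dd$decisions$kept, , drop = FALSE],
                   paths$discards, row.names = FALSE)

  st <- .stage("featurize", prune_missing(compute_descriptors(train_set)))
  desc <- st$value; timings$featurize <- st$elapsed
  y <- train_set$logbb
  if (anyNA(y))
    bbb_error("bbbqsar_schema_error", "training compounds lack logBB values")
  desc <- desc[train_set$id, , drop = FALSE]
  counts$descriptors <- ncol(desc)
  say("featurize: %d descriptors after pruning", ncol(desc))

  spec <- learner_spec(cfg$learner,
                       param_grid = cfg$grid,
                       fixed_params = cfg$params %||% list())

  if (!is.null(cfg$pcc_threshold)) {
    st <- .stage("select", correlation_filter(desc, y, cfg$pcc_threshold))
    selection <- st$value; timings$select <- st$elapsed
    sweep <- NULL
    say("select: threshold %.2f fixed, %d features kept",
        cfg$pcc_threshold, length(selection$selected))
  } else {
    st <- .stage("select", sweep_thresholds(desc, y, cfg$pcc_thresholds,
                                            learner = spec, k = cfg$folds,
                                            seed = cfg$seed,
                                            params = cfg$params))
    sweep <- st$value; timings$select <- st$elapsed
    selection <- sweep$chosen_selection
    say("select: sweep chose threshold %.2f, %d features",
        sweep$chosen_threshold, length(selection$selected))
  }
  counts$features_selected <- length(selection$selected)
  Xsel <- desc[, selection$selected, drop = FALSE]
  paths$features <- file.path(cfg$outdir, "features.csv")
  utils::write.csv(data.frame(id = rownames(Xsel), Xsel, check.names = FALSE),
                   paths$features, row.names = FALSE)

  if (!is.null(cfg$grid)) {
    st <- .stage("train", grid_search(spec, Xsel, y, k = cfg$folds,
                                      seed = cfg$seed))
    gs <- st$value; timings$train <- st$elapsed
    model <- gs$model; cv <- gs$best_cv
    say("train: grid search over %d points, best mean CV R2 %.3f",
        nrow(gs$results), cv$mean_r2)
  } else {
    st <- .stage("train", {
      cv <- cross_validate(spec, Xsel, y, k = cfg$folds, seed = cfg$seed,
                           params = cfg$params, prescale = cfg$prescale)
      model <- train_model(spec, Xsel, y, params = cfg$params,
                           seed = cfg$seed)
      list(cv = cv, model = model)
    })
    cv <- st$value$cv; model <- st$value$model; timings$train <- st$elapsed
    say("train: %s, %d-fold CV mean R2 %.3f, mean MSE %.3f",
        cfg$learner, cfg$folds, cv$mean_r2, cv$mean_mse)
  }
  paths$model <- file.path(cfg$outdir, "model.rds")
  save_model(model, paths$model)

  st <- .stage("evaluate", {
    ev <- list(cv = list(k = cv$k, seed = cv$seed, mean_r2 = cv$mean_r2,
                         mean_mse = cv$mean_mse, per_fold = cv$per_fold))
    cls <- tryCatch(
      evaluate_predictions(y, cv$oof, cfg$logbb_cutoff),
      error = function(e) NULL)
    if (!is.null(cls)) ev$cv_binarized <- cls
    if (!is.null(cfg$test)) {
      test_set <- read_dataset(cfg$test, "csv", cfg$smiles_col,
                               cfg$logbb_col, cfg$id_col)
      test_set <- screen_against_reference(test_set, train_set,
                                           cfg$tanimoto_cutoff)
      counts$test_compounds <- nrow(test_set)
      td <- prune_missing(compute_descriptors(test_set))
      pred <- predict(model, td)
      ev$test <- evaluate_predictions(test_set$logbb, pred, cfg$logbb_cutoff)
    }
    ev
  })
  evaluation <- st$value; timings$evaluate <- st$elapsed
  paths$evaluation <- file.path(cfg$outdir, "evaluation.json")
  jsonlite::write_json(.evaluation_json(evaluation), paths$evaluation,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(cfg$query)) {
    st <- .stage("predict", {
      q <- read_dataset(cfg$query, cfg$query_format, cfg$smiles_col,
                        cfg$logbb_col, cfg$id_col)
      qd <- compute_descriptors(q)
      pred <- predict(model, qd)
      paths$predictions <- file.path(cfg$outdir, "predictions.csv")
      write_predictions(q, pred, paths$predictions,
                        cutoff = cfg$logbb_cutoff)
      length(pred)
    })
    counts$query_predicted <- st$value; timings$predict <- st$elapsed
    say("predict: %d query compounds written", st$value)
  }

  manifest <- list(
    package = "bbbqsar",
    version = as.character(utils::packageVersion("bbbqsar")),
    parameters = cfg[setdiff(names(cfg), c("grid", "params"))],
    grid = cfg$grid, fixed_params = cfg$params,
    input_md5 = as.list(tools::md5sum(
      stats::na.omit(unlist(cfg[c("input", "test", "query")])))),
    counts = counts,
    outputs = unlist(paths),
    timings_sec = lapply(timings, round, 3))
  paths$manifest <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  say("done: artifacts in %s", cfg$outdir)
  invisible(list(model = model, cv = cv, selection = selection,
                 sweep = sweep, evaluation = evaluation, paths = paths,
                 manifest = manifest))
}

# Flatten an evaluation report into JSON-friendly lists.
.evaluation_json <- function(ev) {
  flat_cls <- function(e) list(
    regression = e$regression,
    confusion = unclass(e$confusion),
    classification = {
      m <- e$classification
      list(accuracy = m$accuracy, sensitivity = m$sensitivity,
           specificity = m$specificity, mcc = m$mcc, npv = m$npv,
           ppv = m$ppv, undefined = as.list(m$undefined))
    })
  out <- list(cv = ev$cv)
  if (!is.null(ev$cv_binarized)) out$cv_binarized <- flat_cls(ev$cv_binarized)
  if (!is.null(ev$test)) out$test <- flat_cls(ev$test)
  out
}
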