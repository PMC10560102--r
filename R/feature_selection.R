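# Redundancy filtering by pairwise Pearson correlation with a
# target-relevance keep rule, and the threshold sweep that picks the best
# cutoff by cross-validated R-squared.
#
# The rule: when two descriptors are mutually correlated beyond the
# threshold, the one with the lower |correlation with logBB| is discarded.
# Implemented as a greedy pass in descending relevance order, which enforces
# the rule globally: a descriptor is kept iff its absolute pairwise
# correlation with every already-kept descriptor is at most the threshold.

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: inputs must be equal-length
#' (>= 3) finite vectors, neither constant.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    bbb_error("bbbqsar_schema_error", "vectors differ in length")
  if (length(x) < 3L)
    bbb_error("bbbqsar_schema_error", "need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    bbb_error("bbbqsar_schema_error", "non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    bbb_error("bbbqsar_degenerate_error",
              "constant input has undefined correlation")
  stats::cor(x, y)
}

#' Filter redundant descriptors by pairwise correlation
#'
#' Ranks descriptors by descending absolute Pearson correlation with the
#' target (ties broken by descriptor name), then keeps each descriptor iff
#' its absolute pairwise correlation with every already-kept descriptor is
#' at most `threshold`. Each drop records the most-correlated kept
#' descriptor it conflicted with; by construction that descriptor has
#' relevance at least as high as the dropped one. Constant columns are
#' removed up front with a warning (their correlation is undefined).
#'
#' @param table Numeric matrix (compounds x descriptors), pruned and finite.
#' @param target Numeric response (logBB), one value per row.
#' @param threshold Pairwise |PCC| threshold in (0, 1).
#' @return Object of class `bbb_selection`: list with `threshold`,
#'   `selected` (ordered descriptor names), `relevance` (named |PCC with
#'   target| for every non-constant descriptor), and `dropped_pairs`
#'   (data.frame `kept`, `dropped`, `pcc`).
#' @export
correlation_filter <- function(table, target, threshold) {
  stopifnot(is.matrix(table), nrow(table) == length(target))
  if (!(threshold > 0 && threshold < 1))
    bbb_error("bbbqsar_schema_error", "threshold must be in (0, 1)")
  if (stats::sd(target) == 0)
    bbb_error("bbbqsar_degenerate_error", "constant target")
  sds <- apply(table, 2L, stats::sd)
  constant <- !(is.finite(sds) & sds > 0)
  if (all(constant))
    bbb_error("bbbqsar_degenerate_error", "all descriptors are constant")
  if (any(constant))
    warning(sprintf("%d constant descriptor(s) removed before filtering: %s",
                    sum(constant),
                    paste(colnames(table)[constant], collapse = ", ")))
  x <- table[, !constant, drop = FALSE]
  rel <- abs(as.numeric(stats::cor(x, target)))
  names(rel) <- colnames(x)
  ord <- order(-rel, colnames(x))
  cors <- abs(stats::cor(x))
  kept <- character(0)
  drops <- list()
  for (j in ord) {
    nm <- colnames(x)[j]
    if (length(kept) == 0L) { kept <- nm; next }
    cc <- cors[kept, nm]
    if (any(cc > threshold)) {
      w <- which.max(cc)
      drops[[length(drops) + 1L]] <-
        data.frame(kept = kept[w], dropped = nm, pcc = unname(cc[w]),
                   stringsAsFactors = FALSE)
    } else {
      kept <- c(kept, nm)
    }
  }
  dropped_pairs <- if (length(drops)) do.call(rbind, drops) else
    data.frame(kept = character(0), dropped = character(0), pcc = numeric(0))
  structure(list(threshold = threshold, selected = kept, relevance = rel,
                 dropped_pairs = dropped_pairs),
            class = "bbb_selection")
}

#' @export
print.bbb_selection <- function(x, ...) {
  cat(sprintf("<bbb_selection> threshold %.2f: %d kept, %d dropped\n",
              x$threshold, length(x$selected), nrow(x$dropped_pairs)))
  invisible(x)
}

#' Sweep correlation-filter thresholds and pick the best by CV R-squared
#'
#' For each threshold, runs [correlation_filter()] and then k-fold
#' cross-validation of the learner on the selected descriptors. The fold
#' partition is derived from `seed` alone, so it is identical across
#' thresholds and the comparison is paired. The chosen threshold maximizes
#' mean CV R-squared; ties break toward the smaller feature set, then the
#' lower threshold. Thresholds yielding fewer than 2 descriptors are
#' skipped with a warning.
#'
#' @param table Descriptor matrix; `target` the logBB response.
#' @param target Numeric response vector.
#' @param thresholds Thresholds to try (default 0.1 to 0.9 by 0.1).
#' @param learner A [learner_spec()] (default the LightGBM learner).
#' @param k Folds; `seed` the fold/shuffle seed; `params` optional fixed
#'   hyperparameters passed to [cross_validate()].
#' @param seed Integer seed for the shared fold partition.
#' @param params Optional named list of learner hyperparameters.
#' @return Object of class `bbb_sweep`: list with `results` (data.frame
#'   `threshold`, `n_features`, `mean_r2`, `mean_mse`), `chosen_threshold`,
#'   `chosen_selection`, `selections`, `folds` (the shared fold partition),
#'   and `cv` (per-threshold CV records).
#' @export
sweep_thresholds <- function(table, target, thresholds = seq(0.1, 0.9, by = 0.1),
                             learner = learner_spec("lightgbm"), k = 10,
                             seed = 42, params = NULL) {
  stopifnot(length(thresholds) >= 1L)
  thresholds <- sort(thresholds)
  res <- data.frame(threshold = thresholds, n_features = NA_integer_,
                    mean_r2 = NA_real_, mean_mse = NA_real_)
  selections <- list(); cvs <- list()
  folds <- .make_folds(nrow(table), k, seed)
  for (i in seq_along(thresholds)) {
    th <- thresholds[i]
    sel <- correlation_filter(table, target, th)
    selections[[as.character(th)]] <- sel
    res$n_features[i] <- length(sel$selected)
    if (length(sel$selected) < 2L) {
      warning(sprintf("threshold %.2f yields < 2 features; skipped", th))
      next
    }
    cv <- cross_validate(learner, table[, sel$selected, drop = FALSE], target,
                         k = k, seed = seed, params = params)
    cvs[[as.character(th)]] <- cv
    res$mean_r2[i] <- cv$mean_r2
    res$mean_mse[i] <- cv$mean_mse
  }
  if (all(is.na(res$mean_r2)))
    bbb_error("bbbqsar_degenerate_error", "no threshold produced a usable model")
  ok <- which(!is.na(res$mean_r2))
  best <- ok[order(-res$mean_r2[ok], res$n_features[ok], res$threshold[ok])][1L]
  structure(list(results = res,
                 chosen_threshold = res$threshold[best],
                 chosen_selection = selections[[as.character(res$threshold[best])]],
                 selections = selections, folds = folds, cv = cvs,
                 k = k, seed = seed),
            class = "bbb_sweep")
}

#' @export
print.bbb_sweep <- function(x, ...) {
  cat(sprintf("<bbb_sweep> chosen threshold %.2f (%d features, mean CV R2 %.3f)\n",
              x$chosen_threshold,
              length(x$chosen_selection$selected),
              x$results$mean_r2[x$results$threshold == x$chosen_threshold]))
  print(x$results)
  invisible(x)
}
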