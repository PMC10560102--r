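# Regression metrics (R-squared, MSE), binarization of logBB at the
# conventional permeability cutoff of -1, confusion counting with
# "permeable" as the positive class, and classification metrics
# (sensitivity, specificity, MCC, accuracy, NPV, PPV). Metrics with a zero
# denominator are reported as absent with a reason, never coerced to 0.

.BBB_LEVELS <- c("permeable", "nonpermeable")

#' Coefficient of determination (R-squared)
#'
#' `1 - SS_res/SS_tot` with the total sum of squares taken about the mean of
#' the observed values.
#'
#' @param actual,predicted Equal-length numeric vectors (n >= 2); `actual`
#'   must not be constant.
#' @return Numeric scalar (at most 1; negative when predictions are worse
#'   than the mean).
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    bbb_error("bbbqsar_schema_error", "vectors differ in length")
  if (length(actual) < 2L)
    bbb_error("bbbqsar_schema_error", "need at least 2 observations")
  if (!all(is.finite(actual)) || !all(is.finite(predicted)))
    bbb_error("bbbqsar_schema_error", "non-finite values in input")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0)
    bbb_error("bbbqsar_degenerate_error",
              "constant observed values: R-squared undefined")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Mean squared error
#'
#' @param actual,predicted Equal-length numeric vectors (n >= 1).
#' @return Mean of squared differences (>= 0).
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    bbb_error("bbbqsar_schema_error", "vectors differ in length")
  if (length(actual) < 1L)
    bbb_error("bbbqsar_schema_error", "empty input")
  mean((actual - predicted)^2)
}

#' Classify logBB values as BBB-permeable or not
#'
#' A logBB at or above the cutoff is `"permeable"`; below it,
#' `"nonpermeable"`. The boundary is inclusive: exactly -1.0 is permeable.
#'
#' @param logbb Finite numeric vector of (predicted or observed) logBB.
#' @param cutoff Classification cutoff; default -1.0.
#' @return Character vector of `"permeable"`/`"nonpermeable"`.
#' @export
binarize_logbb <- function(logbb, cutoff = -1.0) {
  if (length(logbb) == 0L) return(character(0))
  if (!all(is.finite(logbb)))
    bbb_error("bbbqsar_schema_error", "non-finite logBB values")
  ifelse(logbb >= cutoff, "permeable", "nonpermeable")
}

#' Confusion counts for binary permeability labels
#'
#' `"permeable"` is the positive class. The four counts partition the
#' evaluated compounds.
#'
#' @param actual,predicted Equal-length character vectors with values
#'   `"permeable"`/`"nonpermeable"`.
#' @return Object of class `bbb_confusion`: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    bbb_error("bbbqsar_schema_error", "vectors differ in length")
  bad <- setdiff(unique(c(actual, predicted)), .BBB_LEVELS)
  if (length(bad) > 0L)
    bbb_error("bbbqsar_schema_error",
              sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  pos <- .BBB_LEVELS[1L]
  structure(list(tp = sum(actual == pos & predicted == pos),
                 tn = sum(actual != pos & predicted != pos),
                 fp = sum(actual != pos & predicted == pos),
                 fn = sum(actual == pos & predicted != pos)),
            class = "bbb_confusion")
}

#' @export
print.bbb_confusion <- function(x, ...) {
  cat(sprintf("<bbb_confusion> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' accuracy `(TP+TN)/total`, negative predictive value `TN/(TN+FN)` and
#' positive predictive value `TP/(TP+FP)`. Any metric with a zero
#' denominator is returned as `NA` and listed in `undefined` with the
#' reason — degenerate evaluation sets never masquerade as perfect ones.
#'
#' @param counts A `bbb_confusion` from [confusion_counts()].
#' @return Object of class `bbb_class_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `mcc`, `npv`, `ppv` (numeric, `NA` when
#'   undefined), `counts`, and `undefined` (named character vector of
#'   reasons).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "bbb_confusion"))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  undefined <- character(0)
  ratio <- function(num, den, name, reason) {
    if (den == 0) {
      undefined[[name]] <<- reason
      NA_real_
    } else num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity", "no actual positives")
  spec <- ratio(tn, tn + fp, "specificity", "no actual negatives")
  acc <- ratio(tp + tn, total, "accuracy", "empty evaluation set")
  npv <- ratio(tn, tn + fn, "npv", "no negative predictions")
  ppv <- ratio(tp, tp + fp, "ppv", "no positive predictions")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    undefined[["mcc"]] <- "a confusion-table margin is zero"
    NA_real_
  } else (tp * tn - fp * fn) / mcc_den
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 mcc = mcc, npv = npv, ppv = ppv, counts = counts,
                 undefined = undefined),
            class = "bbb_class_metrics")
}

#' @export
print.bbb_class_metrics <- function(x, ...) {
  v <- unlist(x[c("accuracy", "sensitivity", "specificity", "mcc", "npv", "ppv")])
  cat("<bbb_class_metrics>\n")
  print(round(v, 4))
  if (length(x$undefined) > 0L)
    cat("undefined:", paste(names(x$undefined), collapse = ", "), "\n")
  invisible(x)
}

#' Full evaluation report: regression metrics plus binarized classification
#'
#' Computes R-squared and MSE on the continuous values, then binarizes both
#' observed and predicted logBB at the cutoff and reports confusion counts
#' and classification metrics.
#'
#' @param actual,predicted Numeric logBB vectors of equal length.
#' @param cutoff Binarization cutoff; default -1.0.
#' @return List with `regression` (`r2`, `mse`, `n`), `confusion`, and
#'   `classification`.
#' @export
evaluate_predictions <- function(actual, predicted, cutoff = -1.0) {
  reg <- list(r2 = r_squared(actual, predicted),
              mse = mse(actual, predicted),
              n = length(actual))
  cc <- confusion_counts(binarize_logbb(actual, cutoff),
                         binarize_logbb(predicted, cutoff))
  list(regression = reg, confusion = cc,
       classification = classification_metrics(cc))
}
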