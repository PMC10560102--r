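# Regression metrics, binarization, confusion counting, classification
# metrics — checked against hand computations and closed forms.

test_that("r_squared and mse match hand computations", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1.0)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0.0)  # predicting the mean
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.5) # 1 - 1/2
  expect_equal(mse(c(0, 1, 2), c(0, 1, 2)), 0.0)
  expect_equal(mse(c(0, 0), c(1, -1)), 1.0)
  expect_equal(mse(c(0, 1, 2), c(0, 1, 1)), 1 / 3)
  expect_error(r_squared(c(1, 1), c(1, 2)), class = "bbbqsar_degenerate_error")
  expect_error(mse(1:3, 1:2), class = "bbbqsar_schema_error")
})

test_that("r_squared and mse agree with brute-force summation on random vectors", {
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(50); p <- a + rnorm(50, 0, 0.5)
    ss_res <- 0; ss_tot <- 0; se <- 0
    for (j in seq_along(a)) {
      ss_res <- ss_res + (a[j] - p[j])^2
      ss_tot <- ss_tot + (a[j] - mean(a))^2
      se <- se + (a[j] - p[j])^2
    }
    expect_equal(r_squared(a, p), 1 - ss_res / ss_tot, tolerance = 1e-12)
    expect_equal(mse(a, p), se / length(a), tolerance = 1e-12)
  }
})

test_that("binarization boundary is inclusive at the cutoff", {
  expect_equal(binarize_logbb(c(-1.0, -1.01, 1.7, -0.2)),
               c("permeable", "nonpermeable", "permeable", "permeable"))
  expect_error(binarize_logbb(c(1, NA)), class = "bbbqsar_schema_error")
  expect_equal(binarize_logbb(numeric(0)), character(0))
})

test_that("confusion counts partition the sample and invert symmetrically", {
  act <- c(rep("permeable", 3), rep("nonpermeable", 2))
  cc <- confusion_counts(act, act)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 3L, tn = 2L, fp = 0L, fn = 0L))
  inv <- ifelse(act == "permeable", "nonpermeable", "permeable")
  ci <- confusion_counts(act, inv)
  expect_equal(ci$fn, 3L); expect_equal(ci$fp, 2L)
  expect_equal(ci$tp + ci$tn + ci$fp + ci$fn, 5L)
  empty <- confusion_counts(character(0), character(0))
  expect_equal(empty$tp + empty$tn + empty$fp + empty$fn, 0L)
  expect_error(confusion_counts("yes", "permeable"),
               class = "bbbqsar_schema_error")
})

test_that("classification metrics evaluate their closed forms", {
  perfect <- classification_metrics(
    confusion_counts(c("permeable", "nonpermeable"),
                     c("permeable", "nonpermeable")))
  for (m in c("accuracy", "sensitivity", "specificity", "mcc", "npv", "ppv"))
    expect_equal(perfect[[m]], 1.0)
  balanced <- structure(list(tp = 25L, tn = 25L, fp = 25L, fn = 25L),
                        class = "bbb_confusion")
  mb <- classification_metrics(balanced)
  expect_equal(mb$mcc, 0.0)
  expect_equal(mb$accuracy, 0.5)
  # 27-compound table evaluated by direct arithmetic
  cc <- structure(list(tp = 3L, tn = 19L, fp = 1L, fn = 4L),
                  class = "bbb_confusion")
  m27 <- classification_metrics(cc)
  expect_equal(m27$sensitivity, 3 / 7)
  expect_equal(m27$specificity, 19 / 20)
  expect_equal(m27$ppv, 3 / 4)
  expect_equal(m27$npv, 19 / 23)
  expect_equal(m27$accuracy, 22 / 27)
  expect_equal(m27$mcc, (3 * 19 - 1 * 4) / sqrt(4 * 7 * 20 * 23))
})

test_that("zero-denominator metrics are flagged absent, never coerced to 0", {
  cc <- confusion_counts(rep("permeable", 4), rep("permeable", 4))
  m <- classification_metrics(cc)
  expect_true(is.na(m$specificity))
  expect_true(is.na(m$npv))
  expect_true(is.na(m$mcc))
  expect_named(m$undefined, c("specificity", "npv", "mcc"), ignore.order = TRUE)
  expect_equal(m$sensitivity, 1.0)
})

test_that("MCC equals the Pearson correlation of the binary label vectors", {
  set.seed(31)
  for (i in 1:60) {
    repeat {
      cc <- structure(as.list(stats::setNames(
        as.integer(sample(0:12, 4, replace = TRUE)),
        c("tp", "tn", "fp", "fn"))), class = "bbb_confusion")
      marg <- with(cc, (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
      if (marg > 0) break
    }
    act <- rep(c(1, 1, 0, 0), times = with(cc, c(tp, fn, tn, fp)))
    pred <- rep(c(1, 0, 0, 1), times = with(cc, c(tp, fn, tn, fp)))
    expect_equal(classification_metrics(cc)$mcc, stats::cor(act, pred),
                 tolerance = 1e-12)
  }
})

test_that("swapping the positive class swaps sensitivity/specificity and ppv/npv", {
  act <- c(rep("permeable", 6), rep("nonpermeable", 9))
  set.seed(41)
  pred <- sample(c("permeable", "nonpermeable"), 15, replace = TRUE)
  m <- classification_metrics(confusion_counts(act, pred))
  flip <- function(x) ifelse(x == "permeable", "nonpermeable", "permeable")
  mf <- classification_metrics(confusion_counts(flip(act), flip(pred)))
  expect_equal(m$sensitivity, mf$specificity)
  expect_equal(m$specificity, mf$sensitivity)
  expect_equal(m$ppv, mf$npv)
  expect_equal(m$npv, mf$ppv)
  expect_equal(m$mcc, mf$mcc)
})
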