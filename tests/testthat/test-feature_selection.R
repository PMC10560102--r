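# Pearson correlation, redundancy filtering with the target-relevance keep
# rule, and the threshold sweep.

test_that("pearson correlation matches closed forms and validates input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_correlation(x, x), 1.0)
  expect_equal(pearson_correlation(x, -x), -1.0)
  # hand computation: cov = 1.5, sd_x = 1, sd_y = sqrt(7/3)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)),
               1.5 / sqrt(7 / 3), tolerance = 1e-10)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 0.9819805,
               tolerance = 1e-7)
  expect_error(pearson_correlation(c(1, 1, 1), x),
               class = "bbbqsar_degenerate_error")
  expect_error(pearson_correlation(1:2, 1:2), class = "bbbqsar_schema_error")
})

test_that("the more target-relevant member of a redundant pair is kept", {
  set.seed(51)
  n <- 60
  good <- rnorm(n)
  y <- 2 * good + rnorm(n, 0, 0.3)
  clone <- good + rnorm(n, 0, 0.05)     # near-copy, less relevant by noise
  other <- rnorm(n)
  x <- cbind(clone = clone, good = good, other = other)
  sel <- correlation_filter(x, y, 0.8)
  expect_true("good" %in% sel$selected)
  expect_false("clone" %in% sel$selected)
  expect_true("other" %in% sel$selected)
  expect_equal(sel$dropped_pairs$kept[sel$dropped_pairs$dropped == "clone"],
               "good")
})

test_that("a loose threshold keeps weakly correlated descriptors", {
  set.seed(52)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- rnorm(60)
  sel <- correlation_filter(x, y, 0.99)
  expect_equal(sort(sel$selected), paste0("d", 1:5))
  expect_equal(nrow(sel$dropped_pairs), 0L)
})

test_that("selection satisfies both invariants against a brute-force check", {
  set.seed(53)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
    # induce some redundancy
    x[, 5] <- 0.9 * x[, 1] + 0.1 * rnorm(40)
    x[, 6] <- -0.95 * x[, 2] + 0.05 * rnorm(40)
    y <- x[, 1] - x[, 2] + rnorm(40, 0, 0.5)
    th <- 0.6
    sel <- correlation_filter(x, y, th)
    cm <- abs(stats::cor(x))
    # kept pairs all within threshold (exhaustive)
    for (a in sel$selected) for (b in sel$selected)
      if (a != b) expect_lte(cm[a, b], th)
    # every dropped feature lost to a kept feature of >= relevance
    if (nrow(sel$dropped_pairs) > 0) {
      for (j in seq_len(nrow(sel$dropped_pairs))) {
        kd <- sel$dropped_pairs[j, ]
        expect_gt(cm[kd$kept, kd$dropped], th)
        expect_gte(sel$relevance[[kd$kept]], sel$relevance[[kd$dropped]])
      }
    }
  }
})

test_that("selection is deterministic and breaks relevance ties by name", {
  set.seed(54)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, c("b", "a", "d", "c")))
  x[, "a"] <- x[, "b"]  # identical columns: equal relevance, tie on name
  y <- x[, "b"] + rnorm(50, 0, 0.2)
  s1 <- correlation_filter(x, y, 0.7)
  s2 <- correlation_filter(x, y, 0.7)
  expect_identical(s1$selected, s2$selected)
  expect_true("a" %in% s1$selected)
  expect_false("b" %in% s1$selected)
})

test_that("block-redundant synthetic data collapses to one feature per block", {
  d <- make_regression_dataset(300, n_signal_features = 3,
                               clones_per_block = 10,
                               intra_block_corr = 0.95, noise_sd = 0.4,
                               seed = 55)
  sel <- correlation_filter(d$x, d$y, 0.8)
  for (b in d$truth$blocks)
    expect_equal(sum(sel$selected %in% b), 1L)
})

test_that("sweep is monotone in feature count, pairs folds, and picks by CV R2", {
  d <- make_regression_dataset(150, clones_per_block = 6,
                               intra_block_corr = 0.9, noise_sd = 0.6,
                               seed = 56)
  sw <- sweep_thresholds(d$x, d$y, thresholds = c(0.2, 0.5, 0.8, 0.95),
                         learner = learner_spec("mlr"), k = 5, seed = 57)
  expect_true(all(diff(sw$results$n_features) >= 0))
  # identical fold partition reused across thresholds
  for (cv in sw$cv) expect_identical(cv$folds, sw$folds)
  best <- max(sw$results$mean_r2, na.rm = TRUE)
  chosen <- sw$results$mean_r2[sw$results$threshold == sw$chosen_threshold]
  expect_equal(chosen, best)
  # single threshold in the list is chosen trivially
  sw1 <- sweep_thresholds(d$x, d$y, thresholds = 0.8,
                          learner = learner_spec("mlr"), k = 5, seed = 57)
  expect_equal(sw1$chosen_threshold, 0.8)
})
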