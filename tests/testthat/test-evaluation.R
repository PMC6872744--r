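test_that("binary metrics implement the strict threshold rule", {
  scores <- c(1, 1, 0, 0); labels <- c(TRUE, TRUE, FALSE, FALSE)
  m <- binary_metrics(scores, labels, 0.5)
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(100, 100, 100))

  # 98 of 100 positives detected -> sensitivity 98%
  scores <- c(rep(0.9, 98), rep(0.1, 2), rep(0.1, 50))
  labels <- c(rep(TRUE, 100), rep(FALSE, 50))
  m <- binary_metrics(scores, labels, 0.5)
  expect_equal(m$sensitivity, 98)
  expect_equal(m$tp, 98); expect_equal(m$fn, 2)

  # everything predicted positive
  m <- binary_metrics(rep(0.9, 10), c(rep(TRUE, 4), rep(FALSE, 6)), 0.5)
  expect_equal(m$sensitivity, 100); expect_equal(m$specificity, 0)

  # strictness: score equal to the threshold is negative
  m <- suppressWarnings(binary_metrics(c(0.5, 0.6), c(TRUE, TRUE), 0.5))
  expect_equal(m$tp, 1)
  expect_warning(m1 <- binary_metrics(c(0.9, 0.2), c(TRUE, TRUE), 0.5), "NaN")
  expect_true(is.nan(m1$specificity))
})

test_that("binary metric identities hold on randomized draws", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    scores <- runif(n)
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    thr <- runif(1)
    m <- binary_metrics(scores, labels, thr)
    expect_equal(m$tp + m$fn, sum(labels))
    expect_equal(m$tn + m$fp, sum(!labels))
    expect_equal(m$sensitivity, 100 * m$tp / (m$tp + m$fn))
    expect_equal(m$specificity, 100 * m$tn / (m$tn + m$fp))
    expect_equal(m$accuracy, 100 * (m$tp + m$tn) / n)
  }
})

test_that("confusion matrix counts predicted x true with validation", {
  classes <- c("A", "B", "C")
  cm <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"), classes)
  expect_equal(unname(diag(cm)), c(1L, 1L, 1L))
  expect_equal(sum(cm), 3)
  cm2 <- confusion_matrix("B", "A", classes)
  expect_equal(cm2["B", "A"], 1L)
  expect_equal(sum(cm2), 1)
  set.seed(4)
  pred <- sample(classes, 40, TRUE); truth <- sample(classes, 40, TRUE)
  cm3 <- confusion_matrix(pred, truth, classes)
  expect_equal(sum(cm3), 40)
  expect_equal(unname(colSums(cm3)), unname(as.integer(table(factor(truth, classes)))))
  expect_error(confusion_matrix("D", "A", classes), "unknown")
})

test_that("multi-class battery: perfect, tie-break and binary consistency", {
  classes <- paste0("C", 1:12)
  probs <- diag(12)[rep(1:12, 3), ]; colnames(probs) <- classes
  truth <- rep(classes, 3)
  mm <- multiclass_metrics(probs, truth)
  expect_equal(mm$accuracy, 100)
  expect_true(all(mm$per_class$sensitivity == 100))
  expect_true(all(mm$per_class$specificity == 100))

  # uniform probabilities -> deterministic first-class prediction
  pu <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("A", "B", "C")))
  mmu <- multiclass_metrics(pu, rep(c("A", "B", "C"), 2))
  expect_equal(sum(mmu$confusion["A", ]), 6)

  # the two-class case reduces to binary_metrics at threshold 0.5
  set.seed(7)
  p1 <- runif(40, 0.01, 0.99)
  probs2 <- cbind(POS = p1, NEG = 1 - p1)
  truth2 <- ifelse(runif(40) < 0.5, "POS", "NEG")
  mm2 <- multiclass_metrics(probs2, truth2)
  bm <- binary_metrics(p1, truth2 == "POS", 0.5)
  expect_equal(mm2$accuracy, bm$accuracy)
  expect_equal(mm2$per_class$sensitivity[1], bm$sensitivity)
  expect_equal(mm2$per_class$specificity[1], bm$specificity)
})

test_that("ROC endpoints, monotonicity and degenerate conventions", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  r0 <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r0$auc, 0)
  rt <- roc_auc(rep(0.4, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(rt$auc, 0.5)
  expect_equal(nrow(rt$points), 2)          # single diagonal segment
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    scores <- round(runif(n), sample(1:3, 1))  # force ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
  expect_error(roc_auc(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
})

test_that("threshold-sweep AUC equals the rank-statistic formulation", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(8:150, 1)
    scores <- if (i %% 2) runif(n) else round(runif(n), 2)  # with/without ties
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, rank_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:5) {
    scores <- round(runif(60), 2)
    labels <- runif(60) < 0.5
    if (!any(labels) || all(labels)) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-9)
  }
})

test_that("top-N accuracy counts true class among the N best guesses", {
  probs <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(top_n_accuracy(probs, "B", 2), 100)
  expect_equal(top_n_accuracy(probs, "B", 1), 0)
  expect_equal(top_n_accuracy(probs, "C", 3), 100)   # n = C is always 100%
  set.seed(8)
  probs <- t(apply(matrix(rnorm(50 * 6), 50), 1, softmax))
  colnames(probs) <- paste0("K", 1:6)
  truth <- sample(colnames(probs), 50, TRUE)
  accs <- vapply(1:6, function(n) top_n_accuracy(probs, truth, n), numeric(1))
  expect_true(all(diff(accs) >= 0))                  # non-decreasing in n
  expect_equal(accs[6], 100)
  # top-1 equals argmax accuracy
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  expect_equal(accs[1], 100 * mean(pred == truth))
  expect_error(top_n_accuracy(probs, truth, 7), "between")
})

test_that("shared-dimension matrix is symmetric with panel sizes on diagonal", {
  k1 <- variant_key(1, 1:100 * 10, "A", "T")
  col <- function(sites) structure(list(sites = sites), class = "mutation_collection")
  same <- shared_dimension_matrix(list(a = col(k1), b = col(k1)))
  expect_true(all(same == 100))
  k2 <- variant_key(2, 1:50 * 10, "C", "G")
  dis <- shared_dimension_matrix(list(a = col(k1), b = col(k2)))
  expect_equal(dis["a", "b"], 0)
  expect_equal(unname(diag(dis)), c(100L, 50L))
  mix <- shared_dimension_matrix(list(a = col(k1), b = col(c(k1[1:30], k2)),
                                      c = col(k2)))
  expect_identical(mix, t(mix))
  expect_equal(mix["a", "b"], 30L)
})

test_that("per-model aggregation reproduces the published summary pairs", {
  ref <- gdl_reference_metrics()
  agg <- aggregate_model_metrics(ref[, c("accuracy", "sensitivity", "specificity")])
  expect_equal(round(agg$mean[agg$metric == "accuracy"], 2), 98.70)
  # the published 0.91 truncates the sample SD 0.9191; agree to one unit in
  # the last printed digit
  expect_lt(abs(agg$sd[agg$metric == "accuracy"] - 0.91), 0.01)
  expect_equal(round(agg$mean[agg$metric == "sensitivity"], 2), 98.36)
  expect_equal(round(agg$sd[agg$metric == "sensitivity"], 2), 1.34)
  expect_equal(round(agg$mean[agg$metric == "specificity"], 2), 99.03)
  expect_equal(round(agg$sd[agg$metric == "specificity"], 4), 0.7404)
  # population (n) SD would NOT reproduce the printed values: the sample
  # (n-1) estimator is the one in use
  n <- nrow(ref)
  pop_sd <- sqrt(mean((ref$accuracy - mean(ref$accuracy))^2))
  expect_false(round(pop_sd, 2) == 0.91)
  # identical values have zero SD; a single model has undefined SD
  expect_equal(aggregate_model_metrics(data.frame(a = c(5, 5, 5)))$sd, 0)
  expect_warning(one <- aggregate_model_metrics(data.frame(a = 5)), "single")
  expect_true(is.nan(one$sd))
})
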