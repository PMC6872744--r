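#' Binary classification metrics
#'
#' Applies the probability-threshold decision rule — predict positive iff
#' the positive-class score is strictly greater than the threshold — and
#' reports the confusion counts with accuracy, sensitivity and specificity
#' as percentages:
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / total`.
#'
#' @param scores Positive-class probabilities.
#' @param labels Truth: logical, or 0/1, or a factor/character vector with
#'   `positive` naming the positive class.
#' @param threshold Decision threshold (default 0.5).
#' @param positive Positive class name when `labels` is character/factor.
#' @return Object of class `binary_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity` (percent), counts `tp`, `tn`, `fp`, `fn`
#'   and the `threshold`. If the truth contains only one class the undefined
#'   rate is `NaN`, with a warning.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5, positive = NULL) {
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  truth <- as_binary_truth(labels, positive)
  pred <- scores > threshold               # strict
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  if (tp + fn == 0) warning("no positive samples in truth; sensitivity is NaN")
  if (tn + fp == 0) warning("no negative samples in truth; specificity is NaN")
  structure(list(
    accuracy = 100 * (tp + tn) / length(scores),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    tp = tp, tn = tn, fp = fp, fn = fn, threshold = threshold
  ), class = "binary_metrics")
}

as_binary_truth <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (is.null(positive)) positive <- unique(labels)[1]
  if (!positive %in% labels && length(unique(labels)) > 1)
    warning("positive class '", positive, "' absent from labels")
  labels == positive
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  (threshold %g)\n",
              x$accuracy, x$sensitivity, x$specificity, x$threshold))
  cat(sprintf("  tp=%d fn=%d tn=%d fp=%d\n", x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Multi-class confusion matrix
#'
#' Rows are predicted classes, columns are true labels, so column sums give
#' per-class test counts.
#'
#' @param pred,truth Character vectors of predicted and true class names.
#' @param classes Ordered class vocabulary.
#' @return Integer matrix `counts[i, j]` = number of samples predicted as
#'   class `i` with true label `j`.
#' @export
confusion_matrix <- function(pred, truth, classes) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  unknown <- setdiff(unique(c(pred, truth)), classes)
  if (length(unknown))
    stop("unknown class name(s): ", paste(unknown, collapse = ", "))
  m <- table(factor(pred, levels = classes), factor(truth, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(predicted = classes, truth = classes))
  out
}

#' Multi-class metric battery
#'
#' Top-1 (argmax) prediction with ties broken by lowest class index.
#' Reports overall accuracy plus one-vs-rest sensitivity and specificity
#' per class, with macro (unweighted mean over classes) and micro
#' (pooled-count) averages. A class absent from the truth has undefined
#' sensitivity; it is excluded from the macro average with a warning.
#'
#' @param probs Probability matrix (samples x classes).
#' @param truth One-hot matrix of the same shape, or a character vector of
#'   class names.
#' @param classes Ordered class names; defaults to `colnames(probs)`.
#' @return List with `accuracy` (percent), `per_class` data frame,
#'   `macro_sensitivity`, `macro_specificity`, `micro_sensitivity`,
#'   `micro_specificity` (percent) and the `confusion` matrix.
#' @export
multiclass_metrics <- function(probs, truth, classes = colnames(probs)) {
  if (is.null(classes)) stop("class names are required")
  if (is.matrix(truth)) {
    if (!identical(dim(probs), dim(truth)))
      stop("probs and truth shapes disagree")
    truth <- classes[max.col(truth, ties.method = "first")]
  }
  pred <- classes[max.col(probs, ties.method = "first")]
  cm <- confusion_matrix(pred, truth, classes)
  n <- length(truth)
  correct <- sum(diag(cm))
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[, i]) - tp
    fp <- sum(cm[i, ]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = classes[i], n = tp + fn,
               sensitivity = 100 * tp / (tp + fn),
               specificity = 100 * tn / (tn + fp),
               tp = tp, fn = fn, fp = fp, tn = tn)
  })
  per <- do.call(rbind, per)
  absent <- per$n == 0
  if (any(absent))
    warning("class(es) absent from truth excluded from macro sensitivity: ",
            paste(per$class[absent], collapse = ", "))
  tps <- per$tp; fns <- per$fn; fps <- per$fp; tns <- per$tn
  list(accuracy = 100 * correct / n,
       per_class = per,
       macro_sensitivity = mean(per$sensitivity[!absent]),
       macro_specificity = mean(per$specificity),
       micro_sensitivity = 100 * sum(tps) / sum(tps + fns),
       micro_specificity = 100 * sum(tns) / sum(tns + fps),
       confusion = cm)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (equal scores are
#' grouped into a single step), accumulating the true- and false-positive
#' rates, and integrates the area under the curve by the trapezoidal rule.
#' The curve runs from (0, 0) to (1, 1) and both coordinates are monotone
#' non-decreasing; with all scores equal the curve is the single diagonal
#' segment and AUC is 0.5.
#'
#' @inheritParams binary_metrics
#' @return Object of class `roc_curve`: list with a `points` data frame
#'   (`threshold`, `fpr`, `tpr`) and the scalar `auc` in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  truth <- as_binary_truth(labels, positive)
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0 || nneg == 0)
    stop("ROC requires both classes present in the truth")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  grp <- cumsum(!duplicated(s))            # ties grouped into one step
  tp <- cumsum(t); fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f over %d threshold step(s)\n",
              x$auc, nrow(x$points) - 1L))
  invisible(x)
}

#' @param x A `roc_curve`.
#' @param mirrored Plot specificity on the x axis against sensitivity on the
#'   y axis (the presentation some reports use) instead of the conventional
#'   FPR/TPR axes; the AUC is unchanged.
#' @param ... Passed to [graphics::plot()].
#' @rdname roc_auc
#' @export
plot.roc_curve <- function(x, mirrored = FALSE, ...) {
  if (mirrored) {
    graphics::plot(1 - x$points$fpr, x$points$tpr, type = "l",
                   xlim = c(1, 0), xlab = "specificity",
                   ylab = "sensitivity", ...)
  } else {
    graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                   xlab = "false positive rate", ylab = "true positive rate", ...)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Top-N accuracy
#'
#' A sample counts as correct when its true class is among the `n`
#' highest-probability classes, ties broken by lowest class index. Top-1 is
#' argmax accuracy and top-C is always 100%.
#'
#' @param probs Probability matrix (samples x classes).
#' @param truth One-hot matrix or character vector of class names.
#' @param n Number of guesses, `1 <= n <= ncol(probs)`.
#' @param classes Ordered class names; defaults to `colnames(probs)`.
#' @return Accuracy percentage.
#' @export
top_n_accuracy <- function(probs, truth, n, classes = colnames(probs)) {
  if (n < 1 || n > ncol(probs)) stop("n must be between 1 and the class count")
  if (is.matrix(truth)) truth <- classes[max.col(truth, ties.method = "first")]
  ti <- match(truth, classes)
  if (anyNA(ti)) stop("truth contains unknown class name(s)")
  hit <- vapply(seq_len(nrow(probs)), function(i) {
    topn <- order(-probs[i, ], seq_len(ncol(probs)))[seq_len(n)]
    ti[i] %in% topn
  }, logical(1))
  100 * mean(hit)
}

#' Shared-dimension matrix across mutation collections
#'
#' Counts, for every pair of collections, the variant sites common to both
#' panels. The diagonal holds the panel sizes; the matrix is symmetric.
#' Large off-diagonal counts flag cancer types whose ranked variant panels
#' overlap heavily.
#'
#' @param collections Named list of [build_collection()] results (>= 2).
#' @return Symmetric integer matrix of shared site counts.
#' @export
shared_dimension_matrix <- function(collections) {
  if (length(collections) < 2) stop("need at least 2 collections")
  nm <- names(collections)
  if (is.null(nm) || any(nm == "")) stop("collections must be named")
  k <- length(collections)
  m <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in i:k) {
    m[i, j] <- m[j, i] <-
      length(intersect(collections[[i]]$sites, collections[[j]]$sites))
  }
  m
}

#' Aggregate per-model metrics
#'
#' Mean and sample standard deviation (n - 1 denominator) of each metric
#' across a battery of binary models — the convention that reproduces the
#' published summary pairs for the twelve cancer-specific classifiers.
#'
#' @param per_model A data frame with numeric metric columns (e.g.
#'   `accuracy`, `sensitivity`, `specificity`; percentages), or a list of
#'   [binary_metrics()] objects.
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`.
#'   With a single model the SD is `NaN`, with a warning.
#' @export
aggregate_model_metrics <- function(per_model) {
  if (is.list(per_model) && !is.data.frame(per_model)) {
    stopifnot(all(vapply(per_model, inherits, logical(1), "binary_metrics")))
    per_model <- do.call(rbind, lapply(per_model, function(m)
      data.frame(accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity)))
  }
  if (nrow(per_model) == 0) stop("no models to aggregate")
  num <- vapply(per_model, is.numeric, logical(1))
  cols <- names(per_model)[num]
  if (nrow(per_model) < 2)
    warning("sample SD undefined for a single model; reporting NaN")
  data.frame(
    metric = cols,
    mean = vapply(cols, function(cn) mean(per_model[[cn]]), numeric(1)),
    sd = vapply(cols, function(cn)
      if (nrow(per_model) < 2) NaN else stats::sd(per_model[[cn]]), numeric(1)),
    row.names = NULL
  )
}

#' Published per-model performance of the twelve cancer-specific classifiers
#'
#' The reported accuracy, sensitivity and specificity (percent) of the
#' original twelve GDL specific models (one cancer type versus healthy,
#' trained on TCGA/1000 Genomes whole-exome variant profiles). Shipped as a
#' reference input for validating aggregation conventions: feeding this
#' table to [aggregate_model_metrics()] must reproduce the published
#' mean/SD summary pairs.
#'
#' @return Data frame with columns `model`, `accuracy`, `sensitivity`,
#'   `specificity` (12 rows).
#' @export
gdl_reference_metrics <- function() {
  data.frame(
    model = c("BLCA", "BRCA", "COAD", "GBM", "KIRC", "LGG",
              "LUSC", "OV", "PRAD", "SKCM", "THCA", "UCEC"),
    accuracy = c(98.43, 98.19, 99.24, 97.81, 100.00, 99.01,
                 100.00, 100.00, 97.47, 98.22, 97.99, 98.02),
    sensitivity = c(98.68, 97.70, 98.97, 96.77, 100.00, 99.07,
                    100.00, 100.00, 95.79, 97.37, 97.96, 98.06),
    specificity = c(98.04, 99.13, 99.40, 98.89, 100.00, 98.94,
                    100.00, 100.00, 99.03, 98.92, 98.04, 98.00)
  )
}
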