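#' Run a complete classification experiment
#'
#' One call covering the three task modes of the pipeline:
#' \describe{
#'   \item{`"specific"`}{one cancer type versus healthy. The feature panel
#'     is the top-`top_k` collection built from the case cohort only.}
#'   \item{`"total"`}{pooled cancer versus healthy, with the panel built
#'     from the pooled cancer cohort under the strict
#'     `min_occurrence` (count > m) rule.}
#'   \item{`"mixture"`}{multi-class across all cancer types (healthy
#'     excluded), same pooled `min_occurrence` panel.}
#' }
#' The cohort is encoded, split per class (`fraction` train), the network
#' fitted, and the held-out test rows scored with the shadow parameters.
#'
#' @param profiles List of [variant_profile()] objects covering every class.
#' @param mode Task mode (see above).
#' @param case_class For `"specific"`: the cancer class to model.
#' @param healthy_class Label of the healthy samples.
#' @param top_k Panel size for `"specific"` mode.
#' @param min_occurrence Strict occurrence floor for pooled panels.
#' @param collection Optional pre-built [build_collection()] panel
#'   overriding the rule above.
#' @param fraction Training fraction for the stratified split.
#' @param seed Seed for the split (and for training when `config` is
#'   `NULL`).
#' @param hidden Hidden-layer widths.
#' @param config A [gdl_config()]; defaults to `gdl_config(seed = seed)`.
#' @param threshold Decision threshold for binary modes.
#' @return Object of class `gdl_experiment`: list with the fitted `model`,
#'   `data`, `split`, `collection` and the test-set `evaluation` (see
#'   [gdl_evaluate()]).
#' @export
gdl_experiment <- function(profiles,
                           mode = c("specific", "total", "mixture"),
                           case_class = NULL, healthy_class = "HEALTHY",
                           top_k = 1000L, min_occurrence = 2,
                           collection = NULL, fraction = 0.8, seed = 1L,
                           hidden = c(64L, 32L, 16L, 8L), config = NULL,
                           threshold = 0.5) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- gdl_config(seed = seed)
  labels <- vapply(profiles, function(p) p$label, character(1))
  healthy <- profiles[labels == healthy_class]
  cancer <- profiles[labels != healthy_class]
  if (mode != "mixture" && length(healthy) == 0)
    stop("no samples labelled '", healthy_class, "' in the cohort")
  if (length(cancer) == 0) stop("no cancer samples in the cohort")

  if (mode == "specific") {
    if (is.null(case_class)) stop("specific mode requires case_class")
    cases <- profiles[labels == case_class]
    if (length(cases) == 0) stop("no samples labelled '", case_class, "'")
    if (is.null(collection))
      collection <- build_collection(cases, top_k = top_k,
                                     source = paste0(case_class, " cases"))
    data <- assemble_binary_task(cases, healthy, collection)
  } else if (mode == "total") {
    if (is.null(collection))
      collection <- build_collection(cancer, min_occurrence = min_occurrence,
                                     source = "pooled cancer cohort")
    relabel <- function(p) { p$label <- "CANCER"; p }
    data <- assemble_binary_task(lapply(cancer, relabel), healthy, collection,
                                 case_label = "CANCER",
                                 control_label = healthy_class)
  } else {
    if (is.null(collection))
      collection <- build_collection(cancer, min_occurrence = min_occurrence,
                                     source = "pooled cancer cohort")
    data <- suppressWarnings(encode_cohort(cancer, collection))
  }
  split <- split_dataset(data, fraction = fraction, seed = seed)
  model <- gdl_fit(data, split, hidden = hidden, config = config)
  evaluation <- gdl_evaluate(model, data, rows = split$test,
                             threshold = threshold)
  structure(list(mode = mode, model = model, data = data, split = split,
                 collection = collection, evaluation = evaluation),
            class = "gdl_experiment")
}

#' @export
print.gdl_experiment <- function(x, ...) {
  cat(sprintf("<gdl_experiment> mode '%s': %d train / %d test, %d site(s)\n",
              x$mode, length(x$split$train), length(x$split$test),
              length(x$collection$sites)))
  ev <- x$evaluation
  if (!is.null(ev$binary)) {
    print(ev$binary)
    cat(sprintf("  AUC %.4f\n", ev$roc$auc))
  } else {
    cat(sprintf("  accuracy %.2f%% over %d classes; top-2 %.2f%%\n",
                ev$metrics$accuracy, length(x$data$classes), ev$top_n[2]))
  }
  invisible(x)
}

#' Evaluate a fitted classifier on a dataset
#'
#' Scores the selected rows with the shadow parameters and computes the
#' metric battery: for two-class models the threshold-rule binary metrics
#' plus the ROC/AUC on the positive-class score; for multi-class models the
#' confusion matrix, per-class/macro/micro metrics and the full top-N
#' accuracy curve.
#'
#' @param model A fitted `gdl_net`.
#' @param data A `gdl_dataset` encoded against the model's collection.
#' @param rows Row indices to evaluate (default: all).
#' @param threshold Binary decision threshold.
#' @return For binary models a list with `binary` ([binary_metrics()]),
#'   `roc` ([roc_auc()]) and the score matrix `probs`; for multi-class a
#'   list with `metrics` ([multiclass_metrics()]), `confusion`, `top_n`
#'   (named vector over N = 1..C) and `probs`.
#' @export
gdl_evaluate <- function(model, data, rows = NULL, threshold = 0.5) {
  stopifnot(inherits(model, "gdl_net"), inherits(data, "gdl_dataset"))
  if (is.null(rows)) rows <- seq_len(nrow(data$X))
  probs <- predict(model, data)[rows, , drop = FALSE]
  truth <- data$classes[max.col(data$Y[rows, , drop = FALSE],
                                ties.method = "first")]
  if (length(data$classes) == 2) {
    scores <- probs[, 1]
    labels <- truth == data$classes[1]
    list(binary = binary_metrics(scores, labels, threshold = threshold),
         roc = roc_auc(scores, labels), probs = probs)
  } else {
    mm <- multiclass_metrics(probs, truth, classes = data$classes)
    tn <- vapply(seq_along(data$classes), function(n)
      top_n_accuracy(probs, truth, n, classes = data$classes), numeric(1))
    names(tn) <- seq_along(data$classes)
    list(metrics = mm, confusion = mm$confusion, top_n = tn, probs = probs)
  }
}
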