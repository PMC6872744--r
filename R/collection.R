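#' Build a frequency-ranked Mutation Collection
#'
#' The Mutation Collection is the ordered reference panel of variant sites
#' that defines the model's feature dimensions. Each site's occurrence count
#' is the number of distinct cohort samples carrying it; sites are ranked by
#' count from high to low, ties broken by genomic order so the ranking is
#' deterministic. Two selection rules are supported: `top_k` keeps the `k`
#' highest-ranked sites (used for the cancer-specific models, typically
#' k = 10000 at full scale), and `min_occurrence` keeps every site whose
#' count is strictly greater than `m` (the rule used for the total-specific
#' and mixture models, with m = 2).
#'
#' @param profiles List of [variant_profile()] objects.
#' @param top_k Keep the first `k` ranked sites (exclusive with
#'   `min_occurrence`).
#' @param min_occurrence Keep sites with occurrence count `> m`, strictly
#'   (exclusive with `top_k`).
#' @param source Free-text description of the source cohort, stored as
#'   provenance.
#' @return An object of class `mutation_collection`: a list with `sites`
#'   (ordered variant keys), `counts` (non-increasing occurrence counts),
#'   `rule` and `source`.
#' @examples
#' p <- list(variant_profile("s1", "A", c("1:100:A:T", "1:200:C:G")),
#'           variant_profile("s2", "A", "1:100:A:T"))
#' build_collection(p, top_k = 1)
#' @export
build_collection <- function(profiles, top_k = NULL, min_occurrence = NULL,
                             source = "cohort") {
  if (length(profiles) == 0) stop("cannot build a collection from an empty cohort")
  if (is.null(top_k) == is.null(min_occurrence))
    stop("specify exactly one of top_k or min_occurrence")
  keys <- unlist(lapply(profiles, function(p) p$variants), use.names = FALSE)
  if (length(keys) == 0) stop("no variant sites in the cohort")
  tab <- table(keys)
  sites <- names(tab)
  counts <- as.integer(tab)
  # rank by count descending, ties by deterministic genomic order
  g <- genomic_order(sites)
  sites <- sites[g]; counts <- counts[g]
  o <- order(-counts)
  sites <- sites[o]; counts <- counts[o]
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (is.na(top_k) || top_k < 1) stop("top_k must be a positive integer")
    if (top_k > length(sites)) {
      warning("requested top_k = ", top_k, " but only ", length(sites),
              " distinct sites exist; keeping all")
      top_k <- length(sites)
    }
    sites <- sites[seq_len(top_k)]; counts <- counts[seq_len(top_k)]
    rule <- list(rule = "top_k", k = top_k)
  } else {
    m <- as.numeric(min_occurrence)
    if (is.na(m) || m < 0) stop("min_occurrence must be >= 0")
    keep <- counts > m          # strictly greater than m
    sites <- sites[keep]; counts <- counts[keep]
    rule <- list(rule = "min_occurrence", m = m)
  }
  structure(list(sites = sites, counts = counts, rule = rule, source = source),
            class = "mutation_collection")
}

#' @export
print.mutation_collection <- function(x, ...) {
  rule <- if (x$rule$rule == "top_k") paste0("top_k(", x$rule$k, ")")
          else paste0("min_occurrence(> ", x$rule$m, ")")
  cat(sprintf("<mutation_collection> %d site(s), rule %s, source: %s\n",
              length(x$sites), rule, x$source))
  if (length(x$counts))
    cat(sprintf("  occurrence counts: max %d, min %d\n",
                max(x$counts), min(x$counts)))
  invisible(x)
}

#' @rdname build_collection
#' @param collection A `mutation_collection`.
#' @param path Output/input TSV path (columns chrom, pos, ref, alt, count).
#' @export
write_collection <- function(collection, path) {
  df <- parse_variant_keys(collection$sites)
  df$count <- collection$counts
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname build_collection
#' @export
read_collection <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(sites = variant_key(df$chrom, df$pos, df$ref, df$alt),
                 counts = as.integer(df$count),
                 rule = list(rule = "file"), source = path),
            class = "mutation_collection")
}

#' Encode one sample against a Mutation Collection
#'
#' Produces the binary feature vector: element `j` is 1 if the sample
#' carries the collection's `j`-th site and 0 otherwise. A sample sharing no
#' site with the collection encodes to the all-zero vector (with a warning,
#' since such a sample carries no usable signal).
#'
#' @param profile A [variant_profile()] or a character vector of variant keys.
#' @param collection A [build_collection()] result.
#' @return Integer vector of 0/1 of length `length(collection$sites)`.
#' @export
encode_profile <- function(profile, collection) {
  variants <- if (inherits(profile, "variant_profile")) profile$variants
              else as.character(profile)
  if (length(collection$sites) == 0) stop("collection is empty")
  x <- as.integer(collection$sites %in% variants)
  if (sum(x) == 0)
    warning("sample shares no site with the collection; encoded as all zeros")
  x
}

#' One-hot encode a class label
#'
#' @param label A class name present in `classes`.
#' @param classes Ordered character vector of class names; the order defines
#'   the one-hot index and is fixed for the lifetime of a model.
#' @return Named integer vector with a single 1 at the label's index.
#' @examples
#' one_hot("BRCA", c("BLCA", "BRCA", "COAD"))
#' @export
one_hot <- function(label, classes) {
  i <- match(label, classes)
  if (is.na(i)) stop("unknown class label '", label, "'")
  v <- integer(length(classes))
  v[i] <- 1L
  names(v) <- classes
  v
}

#' Encode a cohort as a binary feature matrix with one-hot labels
#'
#' @param profiles List of [variant_profile()] objects.
#' @param collection The [build_collection()] panel defining the feature
#'   dimensions.
#' @param classes Ordered class vocabulary; defaults to the labels' order of
#'   first appearance in `profiles`.
#' @return An object of class `gdl_dataset`: list with binary matrix `X`
#'   (samples x sites), one-hot matrix `Y` (samples x classes),
#'   `sample_ids`, `classes` and the `collection` used.
#' @export
encode_cohort <- function(profiles, collection, classes = NULL) {
  stopifnot(length(profiles) > 0)
  labels <- vapply(profiles, function(p) p$label, character(1))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(classes)) classes <- unique(labels)
  if (!all(labels %in% classes))
    stop("profile label(s) outside the class vocabulary: ",
         paste(setdiff(labels, classes), collapse = ", "))
  X <- matrix(0L, nrow = length(profiles), ncol = length(collection$sites),
              dimnames = list(ids, NULL))
  nzero <- 0L
  for (i in seq_along(profiles)) {
    x <- suppressWarnings(encode_profile(profiles[[i]], collection))
    if (sum(x) == 0) nzero <- nzero + 1L
    X[i, ] <- x
  }
  if (nzero > 0)
    warning(nzero, " sample(s) share no site with the collection (all-zero rows)")
  Y <- matrix(0L, nrow = length(labels), ncol = length(classes),
              dimnames = list(ids, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1L
  structure(list(X = X, Y = Y, sample_ids = ids, classes = classes,
                 collection = collection),
            class = "gdl_dataset")
}

#' @export
print.gdl_dataset <- function(x, ...) {
  cat(sprintf("<gdl_dataset> %d sample(s) x %d site(s), %d class(es): %s\n",
              nrow(x$X), ncol(x$X), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits a dataset per class: each class contributes `round(fraction * n)`
#' samples to the training set (clamped so both partitions are non-empty),
#' shuffled by the seed alone, so identical seeds give identical splits.
#'
#' @param data A `gdl_dataset` from [encode_cohort()].
#' @param fraction Training proportion in (0, 1); the reference protocol
#'   uses 0.8.
#' @param seed Integer seed driving the shuffle.
#' @return Object of class `gdl_split`: list with integer `train` and
#'   `test` row indices, `fraction`, `seed`.
#' @export
split_dataset <- function(data, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(data, "gdl_dataset"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  labels <- data$classes[max.col(data$Y, ties.method = "first")]
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("class(es) with fewer than 2 samples cannot be split: ",
         paste(small, collapse = ", "))
  train <- integer(0)
  with_seed(seed, {
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      n_train <- round(fraction * length(rows))
      n_train <- min(max(n_train, 1L), length(rows) - 1L)
      train <- c(train, sample(rows)[seq_len(n_train)])
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_len(nrow(data$X)), train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "gdl_split")
}

#' @export
print.gdl_split <- function(x, ...) {
  cat(sprintf("<gdl_split> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train), length(x$test), x$fraction, x$seed))
  invisible(x)
}

#' Assemble a binary case/control task
#'
#' Builds the dataset for a binary classifier (one cancer type versus
#' healthy, or pooled cancer versus healthy). The feature dimensions come
#' from the supplied collection, which for specific models is built from the
#' case cohort only — control-private sites never become columns, mirroring
#' the data filtering applied to limited selected variation sites.
#'
#' @param case_profiles,control_profiles Non-empty profile lists; sample ids
#'   must not overlap across the two cohorts.
#' @param collection Feature panel (typically [build_collection()] on
#'   `case_profiles`).
#' @param case_label,control_label Class names; default to the cohorts'
#'   labels when unambiguous. The case class is first, so it owns one-hot
#'   index 1 and is the positive class for binary metrics.
#' @return A `gdl_dataset` with `classes = c(case_label, control_label)`.
#' @export
assemble_binary_task <- function(case_profiles, control_profiles, collection,
                                 case_label = NULL, control_label = NULL) {
  if (length(case_profiles) == 0 || length(control_profiles) == 0)
    stop("both cohorts must be non-empty")
  ids_case <- vapply(case_profiles, function(p) p$sample_id, character(1))
  ids_ctrl <- vapply(control_profiles, function(p) p$sample_id, character(1))
  overlap <- intersect(ids_case, ids_ctrl)
  if (length(overlap))
    stop("sample_id(s) appear in both cohorts: ", paste(overlap, collapse = ", "))
  infer_label <- function(profiles, fallback) {
    labs <- unique(vapply(profiles, function(p) p$label, character(1)))
    if (length(labs) == 1) labs else fallback
  }
  case_label <- case_label %||% infer_label(case_profiles, "CASE")
  control_label <- control_label %||% infer_label(control_profiles, "CONTROL")
  relabel <- function(p, lab) { p$label <- lab; p }
  profiles <- c(lapply(case_profiles, relabel, lab = case_label),
                lapply(control_profiles, relabel, lab = control_label))
  encode_cohort(profiles, collection, classes = c(case_label, control_label))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
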