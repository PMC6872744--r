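#' Synthetic cohort configuration
#'
#' Describes a cohort with the statistical structure the classifier
#' assumes: each cancer-like class has a set of recurrent "signature"
#' variant sites carried by its samples with probability `penetrance`, all
#' samples (including healthy ones) carry sites from a shared long tail of
#' `n_background` low-frequency background sites independently at
#' `bg_rate`, and healthy samples carry background sites only. Optional
#' pairwise `signature_overlap` plants shared signature sites between named
#' class pairs, emulating cancer types whose ranked variant panels overlap
#' heavily. Sites are independent Bernoulli draws: no linkage or
#' trinucleotide-context structure is modelled, since the downstream
#' encoding treats sites independently.
#'
#' The defaults mirror the package's standard evaluation cohort: 12 cancer
#' classes plus healthy, 100 samples per class, 200 signature sites per
#' class at penetrance 0.9, and 5000 background sites at rate 0.02. The
#' default overlap structure plants one fully shared pair (UCEC/COAD,
#' fraction 1.0 — the two classes are then indistinguishable in a
#' presence/absence encoding, the regime that separates multi-class from
#' one-vs-healthy performance) plus partial sharing with BRCA (0.6). With
#' independent Bernoulli sites any overlap fraction below 1 leaves a class
#' pair separable through its unique signature sites, so full sharing is
#' the only way to emulate genuinely confusable cancer types.
#'
#' @param classes Cancer-like class names.
#' @param healthy_class Name of the healthy (background-only) class.
#' @param n_per_class Samples per class (healthy included).
#' @param n_signature Signature sites per cancer class.
#' @param penetrance Probability a class sample carries each of its
#'   signature sites.
#' @param n_background Size of the background site universe.
#' @param bg_rate Probability any sample carries each background site.
#' @param signature_overlap `NULL`, or a data frame with columns `class_a`,
#'   `class_b`, `fraction`: the fraction of `class_b`'s signature sites
#'   shared with `class_a` (rounded to the nearest site count).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(classes = c("BLCA", "BRCA", "COAD", "GBM", "KIRC",
                                   "LGG", "LUSC", "OV", "PRAD", "SKCM",
                                   "THCA", "UCEC"),
                       healthy_class = "HEALTHY",
                       n_per_class = 100L, n_signature = 200L,
                       penetrance = 0.9, n_background = 5000L,
                       bg_rate = 0.02,
                       signature_overlap = data.frame(
                         class_a = c("UCEC", "UCEC", "COAD"),
                         class_b = c("COAD", "BRCA", "BRCA"),
                         fraction = c(1.0, 0.6, 0.6)),
                       seed = 1L) {
  classes <- as.character(classes)
  if (anyDuplicated(c(classes, healthy_class)))
    stop("class names must be unique")
  if (!(penetrance >= 0 && penetrance <= 1 && bg_rate >= 0 && bg_rate <= 1))
    stop("penetrance and bg_rate must be probabilities in [0, 1]")
  if (n_per_class < 0 || n_signature < 0 || n_background < 0)
    stop("counts must be >= 0")
  if (!is.null(signature_overlap)) {
    so <- signature_overlap
    if (!all(c("class_a", "class_b", "fraction") %in% names(so)))
      stop("signature_overlap needs columns class_a, class_b, fraction")
    if (any(so$fraction < 0 | so$fraction > 1))
      stop("overlap fractions must lie in [0, 1]")
    if (!all(c(so$class_a, so$class_b) %in% classes))
      stop("signature_overlap references unknown class(es)")
  }
  structure(list(classes = classes, healthy_class = healthy_class,
                 n_per_class = as.integer(n_per_class),
                 n_signature = as.integer(n_signature),
                 penetrance = penetrance,
                 n_background = as.integer(n_background),
                 bg_rate = bg_rate, signature_overlap = signature_overlap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic synthetic site coordinates: cycle the 22 autosomes with
# positions spaced 100 apart so keys never collide.
synthetic_sites <- function(n, offset = 0L) {
  if (n == 0) return(character(0))
  idx <- offset + seq_len(n) - 1L
  chrom <- as.character((idx %% 22L) + 1L)
  pos <- 100L * (idx %/% 22L) + 1L + (idx %% 22L)  # stagger within chrom
  bases <- c("A", "C", "G", "T")
  ref <- bases[(idx %% 4L) + 1L]
  alt <- bases[((idx + 1L) %% 4L) + 1L]
  variant_key(chrom, pos, ref, alt)
}

#' Simulate a synthetic cohort
#'
#' Draws the cohort described by a [sim_config()]: signature site sets per
#' cancer class (with the configured pairwise overlaps planted exactly, by
#' sharing a prefix of the donor class's sites), then per-sample Bernoulli
#' presence draws. Healthy samples draw from the background only.
#'
#' @param cfg A [sim_config()].
#' @return List with `profiles` (a list of [variant_profile()], cancer
#'   classes then healthy, in class order) and `truth` (per-class signature
#'   key sets, the background site universe and per-sample labels).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bg_sites <- synthetic_sites(cfg$n_background)
  signatures <- list()
  for (i in seq_along(cfg$classes)) {
    signatures[[cfg$classes[i]]] <-
      synthetic_sites(cfg$n_signature,
                      offset = cfg$n_background + (i - 1L) * cfg$n_signature)
  }
  if (!is.null(cfg$signature_overlap)) {
    so <- cfg$signature_overlap
    for (r in seq_len(nrow(so))) {
      k <- round(so$fraction[r] * cfg$n_signature)
      if (k > 0) {
        donor <- signatures[[so$class_a[r]]]
        recip <- signatures[[so$class_b[r]]]
        recip[seq_len(k)] <- donor[seq_len(k)]
        if (anyDuplicated(recip))
          stop("overlap specification produces duplicate sites within class ",
               so$class_b[r], "; use consistent fractions across linked pairs")
        signatures[[so$class_b[r]]] <- recip
      }
    }
  }
  all_classes <- c(cfg$classes, cfg$healthy_class)
  profiles <- vector("list", length(all_classes) * cfg$n_per_class)
  labels <- character(length(profiles))
  n <- cfg$n_per_class
  with_seed(cfg$seed, {
    pi <- 0L
    for (cl in all_classes) {
      sig <- if (cl == cfg$healthy_class) character(0) else signatures[[cl]]
      for (j in seq_len(n)) {
        carried_sig <- if (length(sig))
          sig[stats::runif(length(sig)) < cfg$penetrance] else character(0)
        carried_bg <- if (length(bg_sites))
          bg_sites[stats::runif(length(bg_sites)) < cfg$bg_rate] else character(0)
        pi <- pi + 1L
        id <- sprintf("%s_%03d", cl, j)
        profiles[[pi]] <- variant_profile(id, cl, c(carried_sig, carried_bg))
        labels[pi] <- cl
      }
    }
  })
  names(labels) <- vapply(profiles, function(p) p$sample_id, character(1))
  list(profiles = profiles,
       truth = list(signatures = signatures, background = bg_sites,
                    labels = labels, config = cfg))
}

#' Write a simulated cohort to disk
#'
#' Emits one minimal VCF 4.2 file per sample plus a headered manifest TSV
#' (`sample_id`, `path`, `label`), and optionally the ground truth as a TSV
#' of per-class signature sites. Given the same cohort the VCF bodies are
#' byte-identical across calls, and reloading through [load_cohort()]
#' round-trips to identical variant sets.
#'
#' @param profiles List of [variant_profile()] objects (e.g. from
#'   [simulate_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @param truth Optional truth list from [simulate_cohort()]; written to
#'   `truth.tsv`.
#' @return The manifest data frame (with a `classes` attribute), invisibly;
#'   it is also written to `manifest.tsv` in `out_dir`.
#' @export
write_cohort <- function(profiles, out_dir, truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  labels <- vapply(profiles, function(p) p$label, character(1))
  rel <- file.path("vcf", paste0(ids, ".vcf"))
  for (i in seq_along(profiles))
    write_minimal_vcf(profiles[[i]]$variants, file.path(out_dir, rel[i]),
                      sample_id = ids[i])
  man <- data.frame(sample_id = ids, path = rel, label = labels)
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    rows <- do.call(rbind, lapply(names(truth$signatures), function(cl) {
      df <- parse_variant_keys(truth$signatures[[cl]])
      if (nrow(df)) cbind(class = cl, df) else NULL
    }))
    if (!is.null(rows))
      utils::write.table(rows, file.path(out_dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  man$path <- file.path(out_dir, rel)
  attr(man, "classes") <- unique(labels)
  invisible(man)
}
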