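#' Read one sample's point mutations from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped, via \pkg{vcfR}) into a set of
#' variant keys. Multi-allelic records are split into one key per alternate
#' allele; records whose FILTER is neither `PASS` nor `.` are dropped by
#' default; symbolic or breakend alternate alleles (e.g. `<DEL>`) are skipped
#' with a warning giving the skipped count. Genotype columns are ignored:
#' the presence of a record means the sample carries the variant.
#'
#' @param path Path to a VCF file.
#' @param pass_only Keep only records with FILTER `PASS` or `.` (default
#'   `TRUE`; the upstream calling pipeline's filter semantics vary, so this
#'   is configurable).
#' @return Character vector of unique variant keys.
#' @seealso [load_cohort()], [variant_key()]
#' @export
read_variant_file <- function(path, pass_only = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcf@fix   # always a matrix, even for a single record
  if (is.null(fix) || nrow(fix) == 0) {
    warning("VCF '", path, "' contains no variant records")
    return(character(0))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  if (pass_only) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
    fix <- fix[keep, , drop = FALSE]
  }
  if (nrow(fix) == 0) {
    warning("VCF '", path, "' has no records passing FILTER")
    return(character(0))
  }
  # split multi-allelic ALT fields into one row per allele
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nalt <- lengths(alts)
  chrom <- rep(fix$CHROM, nalt)
  pos <- rep(fix$POS, nalt)
  ref <- rep(toupper(fix$REF), nalt)
  alt <- toupper(unlist(alts))
  symbolic <- grepl("[<>\\[\\]]", alt) | alt == "*" | !grepl("^[ACGTN]+$", alt) |
    !grepl("^[ACGTN]+$", ref)
  if (any(symbolic))
    warning("skipped ", sum(symbolic), " symbolic/non-sequence allele(s) in '",
            path, "'")
  keep <- !symbolic
  if (!any(keep)) return(character(0))
  unique(variant_key(chrom[keep], pos[keep], ref[keep], alt[keep]))
}

#' Read a cohort manifest
#'
#' The manifest is a headered TSV with columns `sample_id`, `path`, `label`.
#' Relative paths are resolved against the manifest's directory. The order
#' of first appearance of labels fixes the class vocabulary, and with it the
#' one-hot index order used everywhere downstream.
#'
#' @param path Path to the manifest TSV.
#' @return A data frame with columns `sample_id`, `path`, `label` and a
#'   `classes` attribute giving the ordered class vocabulary.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "path", "label")
  if (!all(required %in% names(man)))
    stop("manifest must have columns sample_id, path, label")
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  validate_manifest(man)
}

validate_manifest <- function(man) {
  dup <- duplicated(man$sample_id)
  if (any(dup))
    stop("duplicate sample_id(s) in manifest: ",
         paste(unique(man$sample_id[dup]), collapse = ", "))
  if (is.null(attr(man, "classes")))
    attr(man, "classes") <- unique(man$label)
  if (!all(man$label %in% attr(man, "classes")))
    stop("manifest label(s) outside the declared class vocabulary")
  man
}

#' Load a cohort of variant profiles
#'
#' Reads every file referenced by a manifest into a [variant_profile()],
#' preserving manifest order, and reports per-class sample counts.
#'
#' @param manifest A manifest data frame (see [read_manifest()]) or a path
#'   to a manifest TSV.
#' @param pass_only Passed to [read_variant_file()].
#' @param quiet Suppress the per-class count message.
#' @return List of `variant_profile` objects, one per manifest row.
#' @export
load_cohort <- function(manifest, pass_only = TRUE, quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("variant file missing for sample(s): ",
         paste(manifest$sample_id[missing], collapse = ", "))
  profiles <- lapply(seq_len(nrow(manifest)), function(i) {
    variant_profile(manifest$sample_id[i], manifest$label[i],
                    read_variant_file(manifest$path[i], pass_only = pass_only))
  })
  if (!quiet) {
    counts <- table(manifest$label)
    message("loaded ", nrow(manifest), " profile(s): ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  profiles
}

#' Write variant keys as a normalized TSV
#'
#' @param variants Character vector of variant keys, or a `variant_profile`.
#' @param path Output TSV path (columns chrom, pos, ref, alt).
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  if (inherits(variants, "variant_profile")) variants <- variants$variants
  df <- parse_variant_keys(variants)
  df <- df[genomic_order(variants), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal deterministic VCF 4.2 writer used by the simulator; one sample's
# presence/absence call set, genomically sorted, FILTER PASS.
write_minimal_vcf <- function(variants, path, sample_id = "SAMPLE") {
  df <- parse_variant_keys(variants)
  ord <- if (length(variants)) genomic_order(variants) else integer(0)
  df <- df[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=gdlnet_simulator"),
    paste0("##sample=", sample_id),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(df)) {
    paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", ".", sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
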