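#' Construct variant keys
#'
#' A variant key is the identity of one point mutation: chromosome, 1-based
#' position, reference allele and a single alternate allele. Keys are stored
#' as strings of the form `"chrom:pos:ref:alt"` with the chromosome name
#' normalized (a leading `"chr"` prefix is stripped, so `"chr17"` and `"17"`
#' compare equal) and alleles upper-cased. Multi-allelic records must be
#' split into one key per alternate allele before construction.
#'
#' @param chrom Chromosome names (character).
#' @param pos 1-based positions (VCF convention).
#' @param ref Reference alleles, strings over A/C/G/T/N.
#' @param alt Alternate alleles, one allele per key (no commas).
#' @return Character vector of normalized variant keys.
#' @examples
#' variant_key(c("chr17", "17"), c(7674220, 7674220), "C", "T")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- normalize_chrom(as.character(chrom))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("variant positions must be integers >= 1 (1-based, VCF convention)")
  bad <- !grepl("^[ACGTN]+$", ref) | !grepl("^[ACGTN]+$", alt)
  if (any(bad))
    stop("ref/alt alleles must be non-empty strings over {A,C,G,T,N}; offending: ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("a variant key carries exactly one alt allele; split multi-allelic records first")
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname variant_key
#' @param keys Character vector of keys as produced by [variant_key()].
#' @return `parse_variant_keys()` returns a data frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_keys <- function(keys) {
  if (length(keys) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  parts <- strsplit(keys, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop("malformed variant key(s)")
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
             ref = m[, 3], alt = m[, 4])
}

normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", chrom)
}

# Numeric rank for autosomes, then X/Y/MT, then other contigs alphabetically.
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom %in% "X"] <- 23
  r[chrom %in% "Y"] <- 24
  r[chrom %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26
  r
}

#' Order variant keys genomically
#'
#' Sorts by chromosome (autosomes numerically, then X, Y, MT, then other
#' contigs alphabetically), position, ref and alt. This deterministic order
#' is the tie-breaker used when ranking collection sites with equal counts.
#'
#' @param keys Character vector of variant keys.
#' @return Integer permutation that sorts `keys`.
#' @export
genomic_order <- function(keys) {
  df <- parse_variant_keys(keys)
  order(chrom_rank(df$chrom), df$chrom, df$pos, df$ref, df$alt)
}

#' One sample's variant profile
#'
#' Bundles a sample identifier, its class label and the set of variant keys
#' it carries. Duplicate keys collapse: the downstream encoding is pure
#' presence/absence, so genotype and multiplicity are deliberately ignored.
#'
#' @param sample_id Sample identifier string.
#' @param label Class label (e.g. a cancer type abbreviation or `"HEALTHY"`).
#' @param variants Character vector of variant keys (deduplicated).
#' @return An object of class `variant_profile`.
#' @export
variant_profile <- function(sample_id, label, variants) {
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            is.character(label), length(label) == 1)
  structure(list(sample_id = sample_id, label = label,
                 variants = unique(as.character(variants))),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat(sprintf("<variant_profile> %s [%s]: %d variant site(s)\n",
              x$sample_id, x$label, length(x$variants)))
  invisible(x)
}
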