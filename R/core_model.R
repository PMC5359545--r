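#' @title Impact-tier taxonomy
#' @description Fixed mapping from SnpEff-style functional classes to the
#'   four severity tiers used throughout the funnel. The taxonomy is total:
#'   every class maps to exactly one tier, and classes not individually
#'   itemised by the annotator are absorbed by `low_other` / `modifier`.
#' @format Named character vector: names are the 12 functional-class
#'   labels, values are tiers in `c("HIGH","MODERATE","LOW","MODIFIER")`.
#' @export
impact_taxonomy <- c(
  stop_gain             = "HIGH",
  start_stop_loss       = "HIGH",
  splice_donor_acceptor = "HIGH",
  exon_deletion         = "HIGH",
  frameshift            = "HIGH",
  rare_amino_acid       = "HIGH",
  codon_alteration      = "MODERATE",
  missense              = "MODERATE",
  splice_branch         = "MODERATE",
  utr_deletion          = "MODERATE",
  low_other             = "LOW",
  modifier              = "MODIFIER"
)

#' Severity order of impact tiers, most severe first.
#' @export
impact_tiers <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Functional classes recognised by the taxonomy
#' @return Character vector of the 12 class labels.
#' @export
functional_classes <- function() names(impact_taxonomy)

#' Map a functional class to its impact tier
#'
#' @param functional_class Character vector of class labels (any of
#'   [functional_classes()]).
#' @return Character vector of tiers, one per input label.
#' @examples
#' impact_tier_of("frameshift")  # "HIGH"
#' impact_tier_of("missense")    # "MODERATE"
#' @export
impact_tier_of <- function(functional_class) {
  bad <- setdiff(unique(functional_class), names(impact_taxonomy))
  if (length(bad) > 0L) {
    stop("unknown functional class(es): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(names(impact_taxonomy), collapse = ", "),
         call. = FALSE)
  }
  unname(impact_taxonomy[functional_class])
}

#' Rank of an impact tier (1 = most severe)
#' @param tier Character vector of tiers.
#' @return Integer ranks.
#' @keywords internal
tier_rank <- function(tier) {
  r <- match(tier, impact_tiers)
  if (anyNA(r)) {
    stop("unknown impact tier(s): ",
         paste(unique(tier[is.na(r)]), collapse = ", "),
         "; valid tiers are: ", paste(impact_tiers, collapse = ", "),
         call. = FALSE)
  }
  r
}

# Alleles are either nucleotide strings or symbolic tokens such as "wt" /
# "delCT" (published genotype tables print symbolic alleles with no sequence
# context). ":" is reserved as the key separator.
.valid_allele <- function(x) {
  nzchar(x) & !grepl("[:[:space:]]", x)
}

#' Canonical variant key
#'
#' Builds the identity key `chrom:pos:ref:alt` of a biallelic variant.
#' Equal variants read from different files yield equal keys; SNVs and
#' indels at the same position are distinct.
#'
#' @param chrom Sequence name, or a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt` (vectorised use).
#' @param pos 1-based position (ignored when `chrom` is a data.frame).
#' @param ref,alt Reference / alternate alleles.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    v <- chrom
    return(variant_key(v$chrom, v$pos, v$ref, v$alt))
  }
  stopifnot(length(chrom) == length(pos),
            length(chrom) == length(ref),
            length(chrom) == length(alt))
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Build a variant table
#'
#' Validates and assembles the per-variant metadata used inside a
#' [callset()]. Multiallelic records must be decomposed into one row per
#' alternate allele before this point (see [read_vcf()]).
#'
#' @param chrom,pos,ref,alt Vectors describing each biallelic variant.
#' @param gene Gene symbol per variant (`NA` when unannotated).
#' @param functional_class Class label per variant (default `low_other`).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `functional_class`, `impact_tier`, `key`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gene = NA_character_,
                          functional_class = "low_other") {
  pos <- as.integer(pos)
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  if (length(chrom) == 0L || length(pos) == 0L) n <- 0L
  pos <- rep_len(pos, n)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  gene <- rep_len(as.character(gene), n)
  functional_class <- rep_len(functional_class, n)
  if (any(pos < 1L, na.rm = TRUE) || anyNA(pos) && n > 0L)
    stop("variant positions must be integers >= 1", call. = FALSE)
  if (n > 0L && any(!.valid_allele(ref) | !.valid_allele(alt)))
    stop("alleles must be non-empty and free of ':' and whitespace",
         call. = FALSE)
  if (any(ref == alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  df <- data.frame(
    chrom = as.character(chrom), pos = pos,
    ref = as.character(ref), alt = as.character(alt),
    gene = gene,
    functional_class = functional_class,
    impact_tier = if (n > 0L) impact_tier_of(functional_class) else character(0),
    stringsAsFactors = FALSE
  )
  df$key <- variant_key(df)
  if (anyDuplicated(df$key))
    stop("duplicate variant keys: ",
         paste(unique(df$key[duplicated(df$key)]), collapse = ", "),
         call. = FALSE)
  df
}

#' Construct a CallSet
#'
#' A CallSet is the central container of the pipeline: an ordered variant
#' table plus a variants x samples matrix of alternate-allele counts.
#' Genotypes are unphased diploid dosages in `{0, 1, 2}`; `NA` encodes a
#' MISSING call, which is distinct from dosage 0.
#'
#' @param variants A data.frame from [variant_table()].
#' @param samples Character vector of unique sample ids.
#' @param geno Integer matrix, `nrow(variants)` x `length(samples)`, of
#'   alt-allele counts with `NA` for missing calls.
#' @return An object of class `CallSet`.
#' @export
callset <- function(variants, samples, geno) {
  samples <- as.character(samples)
  if (anyDuplicated(samples))
    stop("sample ids must be unique", call. = FALSE)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants) || ncol(geno) != length(samples))
    stop("geno matrix must be n_variants x n_samples", call. = FALSE)
  ok <- geno %in% c(0L, 1L, 2L, NA_integer_)
  if (!all(ok))
    stop("alt-allele counts must be 0, 1, 2 or NA (missing)", call. = FALSE)
  rownames(geno) <- variants$key
  colnames(geno) <- samples
  structure(
    list(variants = variants, samples = samples, geno = geno),
    class = "CallSet"
  )
}

#' Empty CallSet over a set of samples
#' @param samples Character vector of sample ids.
#' @return A `CallSet` with zero variants.
#' @export
empty_callset <- function(samples = character(0)) {
  callset(variant_table(character(0), integer(0), character(0), character(0)),
          samples,
          matrix(integer(0), nrow = 0, ncol = length(samples)))
}

#' Number of variants in a CallSet
#' @param x A `CallSet`.
#' @export
n_variants <- function(x) nrow(x$variants)

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("CallSet: %d variant(s) x %d sample(s)\n",
              n_variants(x), length(x$samples)))
  if (n_variants(x) > 0L) {
    tiers <- table(factor(x$variants$impact_tier, levels = impact_tiers))
    cat("  impact tiers:",
        paste(sprintf("%s=%d", names(tiers), as.integer(tiers)),
              collapse = " "), "\n")
  }
  if (length(x$samples) > 0L)
    cat("  samples:", paste(utils::head(x$samples, 8), collapse = ", "),
        if (length(x$samples) > 8) "...", "\n")
  invisible(x)
}

#' Subset a CallSet by variant keys (keeps input order of the CallSet)
#' @param x A `CallSet`.
#' @param keys Character vector of variant keys to keep.
#' @return A `CallSet`.
#' @export
subset_variants <- function(x, keys) {
  keep <- x$variants$key %in% keys
  callset(x$variants[keep, , drop = FALSE], x$samples,
          x$geno[keep, , drop = FALSE])
}

#' Restrict a CallSet to a subset of samples
#' @param x A `CallSet`.
#' @param samples Sample ids to keep; must all be present.
#' @return A `CallSet`.
#' @export
subset_samples <- function(x, samples) {
  missing <- setdiff(samples, x$samples)
  if (length(missing) > 0L)
    stop("sample id(s) not in CallSet: ", paste(missing, collapse = ", "),
         call. = FALSE)
  callset(x$variants, samples, x$geno[, samples, drop = FALSE])
}

#' Alt-allele counts of one variant across samples
#' @param x A `CallSet`.
#' @param key A single variant key.
#' @return Named integer vector (NA = missing call).
#' @export
genotypes_of <- function(x, key) {
  i <- match(key, x$variants$key)
  if (is.na(i)) stop("variant key not in CallSet: ", key, call. = FALSE)
  x$geno[i, ]
}

#' Phenotype table constructor
#'
#' @param sample_id Character vector of sample ids.
#' @param status One of `"affected"`, `"unaffected"`, `"unknown"` per sample.
#' @return data.frame with columns `sample_id`, `status`.
#' @export
phenotypes <- function(sample_id, status) {
  sample_id <- as.character(sample_id)
  status <- rep_len(as.character(status), length(sample_id))
  bad <- setdiff(unique(status), c("affected", "unaffected", "unknown"))
  if (length(bad) > 0L)
    stop("phenotype status must be affected/unaffected/unknown; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("one phenotype status per sample id", call. = FALSE)
  data.frame(sample_id = sample_id, status = status, stringsAsFactors = FALSE)
}
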