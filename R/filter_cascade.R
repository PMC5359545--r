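#' Stage names of the prioritization funnel, in cascade order.
#' @export
funnel_stages <- c("trio", "species_specific", "phenotype_segregation",
                   "gene_list")

#' Variants called non-reference within a trio
#'
#' First funnel stage: keeps variants for which at least one trio member
#' carries at least one alternate allele (MISSING calls carry nothing),
#' and drops all non-trio samples from the output.
#'
#' @param x A `CallSet`.
#' @param trio_ids Character vector of three sample ids (sire, dam,
#'   affected offspring, in any order).
#' @return A `CallSet` over the trio samples only.
#' @export
trio_sites <- function(x, trio_ids) {
  stopifnot(length(trio_ids) == 3L)
  x <- subset_samples(x, trio_ids)
  carries <- rowSums(x$geno >= 1L, na.rm = TRUE) > 0L
  subset_variants(x, x$variants$key[carries])
}

#' Subtract variants shared with another cohort
#'
#' Removes from `target` every variant whose key is carried (alt-allele
#' count >= 1 in any sample) by the `other` CallSet. This is key-level
#' site sharing, not genotype-identity: cross-species subtraction compares
#' site lists. Idempotent, and anti-monotone in `other`.
#'
#' @param target,other `CallSet` objects keyed canonically.
#' @return `target` without the shared variants.
#' @export
subtract_shared <- function(target, other) {
  carried <- rowSums(other$geno >= 1L, na.rm = TRUE) > 0L
  shared <- other$variants$key[carried]
  subset_variants(target, setdiff(target$variants$key, shared))
}

#' Recessive segregation filter within a trio
#'
#' Keeps exactly the variants whose genotypes fit an autosomal recessive
#' model in the trio: affected offspring homozygous alternate (dosage 2)
#' and both unaffected parents heterozygous (dosage 1). A MISSING call in
#' any trio member disqualifies the variant (conservative; no imputation).
#'
#' @param x A `CallSet` containing the three samples.
#' @param sire,dam,affected Distinct sample ids.
#' @return A `CallSet`.
#' @export
recessive_trio_filter <- function(x, sire, dam, affected) {
  ids <- c(sire, dam, affected)
  if (anyDuplicated(ids))
    stop("sire, dam and affected ids must be distinct", call. = FALSE)
  missing <- setdiff(ids, x$samples)
  if (length(missing) > 0L)
    stop("sample id(s) not in CallSet: ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- x$geno[, ids, drop = FALSE]
  ok <- !is.na(g[, 1L]) & !is.na(g[, 2L]) & !is.na(g[, 3L]) &
        g[, 1L] == 1L & g[, 2L] == 1L & g[, 3L] == 2L
  subset_variants(x, x$variants$key[ok])
}

#' Filter a CallSet by minimum impact tier
#'
#' @param x A `CallSet`.
#' @param minimum_tier Least severe tier to keep, under the order
#'   HIGH > MODERATE > LOW > MODIFIER. `"MODIFIER"` is the identity.
#' @return A `CallSet`.
#' @export
select_by_impact <- function(x, minimum_tier) {
  cutoff <- tier_rank(minimum_tier)
  stopifnot(length(cutoff) == 1L)
  keep <- tier_rank(x$variants$impact_tier) <= cutoff
  subset_variants(x, x$variants$key[keep])
}

#' Intersect a CallSet with a disease-gene list
#'
#' Keeps variants annotated to a gene in `genes` (case-insensitive).
#' Variants without a gene symbol are never retained. An empty gene list
#' is rejected: it would silently empty the funnel.
#'
#' @param x A `CallSet`.
#' @param genes Character vector of gene symbols (see [read_gene_list()]).
#' @return A `CallSet`.
#' @export
intersect_gene_list <- function(x, genes) {
  genes <- unique(ic_norm(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    stop("gene list is empty; refusing to intersect", call. = FALSE)
  g <- ic_norm(x$variants$gene)
  keep <- !is.na(x$variants$gene) & g %in% genes
  subset_variants(x, x$variants$key[keep])
}

# Count variants of a CallSet per functional class (named integer vector
# over all 12 classes).
.class_counts <- function(x) {
  tab <- table(factor(x$variants$functional_class,
                      levels = functional_classes()))
  stats::setNames(as.integer(tab), functional_classes())
}

#' Construct a funnel report
#'
#' A FunnelReport is a functional-class x stage grid of variant counts
#' documenting attrition through the cascade. Reports produced by
#' [run_funnel()] satisfy monotonicity (counts never increase along the
#' stage order, per class). Published grids transcribed from effect-level
#' annotator output can violate variant-level monotonicity (each alternate
#' allele may hit several gene isoforms), so validation can be switched
#' off for pre-filled reports.
#'
#' @param counts Integer matrix with `rownames = functional_classes()` and
#'   `colnames` a prefix (or all) of [funnel_stages].
#' @param validate Check per-class monotonicity across stages.
#' @return An object of class `FunnelReport`.
#' @export
funnel_report <- function(counts, validate = TRUE) {
  counts <- as.matrix(counts)
  if (!all(rownames(counts) == functional_classes()))
    stop("report rows must be the 12 functional classes, in taxonomy order",
         call. = FALSE)
  if (!all(colnames(counts) %in% funnel_stages))
    stop("unknown stage name(s): ",
         paste(setdiff(colnames(counts), funnel_stages), collapse = ", "),
         call. = FALSE)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L, na.rm = TRUE))
    stop("stage counts must be non-negative", call. = FALSE)
  if (validate && ncol(counts) > 1L) {
    nonincreasing <- apply(counts, 1L, function(r) all(diff(r) <= 0L))
    if (!all(nonincreasing))
      stop("funnel counts increase along stages for class(es): ",
           paste(rownames(counts)[!nonincreasing], collapse = ", "),
           call. = FALSE)
  }
  structure(list(stages = colnames(counts), counts = counts),
            class = "FunnelReport")
}

#' @export
print.FunnelReport <- function(x, ...) {
  cat(render_funnel(x)$text, sep = "\n")
  invisible(x)
}

#' Run the five-step prioritization funnel
#'
#' Composes the cascade in its canonical order: (1) sites non-reference in
#' the trio, (2) subtraction of variants shared with the sister-species
#' outgroup, (3) subtraction of variants shared with the conspecific
#' relative panel, (4) autosomal-recessive segregation within the trio,
#' (5) intersection with the disease-gene list. Steps 2 and 3 together
#' form the report's `species_specific` stage.
#'
#' @param trio_callset `CallSet` holding the trio samples (other samples
#'   are dropped at stage 1).
#' @param outgroup_callset `CallSet` of the outgroup individual(s).
#' @param panel_callset `CallSet` of the conspecific-relative panel.
#' @param sire,dam,affected Trio sample ids.
#' @param genes Gene list for stage 5.
#' @return List with `callset` (survivors of all stages) and `report`
#'   (a [funnel_report()]).
#' @export
run_funnel <- function(trio_callset, outgroup_callset, panel_callset,
                       sire, dam, affected, genes) {
  s1 <- trio_sites(trio_callset, c(sire, dam, affected))
  s2 <- subtract_shared(s1, outgroup_callset)
  s3 <- subtract_shared(s2, panel_callset)
  s4 <- recessive_trio_filter(s3, sire, dam, affected)
  s5 <- intersect_gene_list(s4, genes)
  counts <- cbind(
    trio = .class_counts(s1),
    species_specific = .class_counts(s3),
    phenotype_segregation = .class_counts(s4),
    gene_list = .class_counts(s5)
  )
  list(callset = s5, report = funnel_report(counts))
}
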