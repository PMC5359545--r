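# Shared helpers for building tiny call sets and locating packaged fixtures.

fx <- function(name) {
  path <- system.file("extdata", name, package = "triofunnel")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

# Quick CallSet: geno is a matrix (variants x samples) or vector; variants
# are SNVs on one mock chromosome unless ref/alt given.
make_cs <- function(geno, samples = NULL, gene = NA_character_,
                    class = "low_other", chrom = "chr1",
                    pos = NULL, ref = "A", alt = "T") {
  geno <- rbind(geno)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(geno)))
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 10L
  callset(variant_table(chrom, pos, ref, alt, gene, class), samples, geno)
}

trio_phen <- function(sire = "sire", dam = "dam", aff = "kid") {
  phenotypes(c(sire, dam, aff), c("unaffected", "unaffected", "affected"))
}

# Literal double-loop oracle for the recessive concordance predicates.
oracle_concordance_status <- function(calls, status) {
  if (all(is.na(calls))) return("uninformative")
  excluded <- FALSE
  for (i in seq_along(calls)) {
    if (is.na(calls[i])) next
    if (status[i] == "affected" && calls[i] != 2) excluded <- TRUE
    if (status[i] == "unaffected" && calls[i] == 2) excluded <- TRUE
  }
  if (excluded) "excluded_genotype" else "retained"
}

# Allele-drawing oracle for offspring dosage attainability.
oracle_child_possible <- function(child, sire, dam) {
  draws <- function(g) switch(as.character(g), "0" = 0, "1" = c(0, 1), "2" = 1)
  any(outer(draws(sire), draws(dam), `+`) == child)
}
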