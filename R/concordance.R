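.verdict <- function(key, status, offending = NULL, note = "") {
  if (is.null(offending))
    offending <- data.frame(sample_id = character(0), reason = character(0),
                            stringsAsFactors = FALSE)
  structure(list(key = key, status = status,
                 offending_samples = offending, note = note),
            class = "ConcordanceVerdict")
}

#' @export
print.ConcordanceVerdict <- function(x, ...) {
  cat(sprintf("%s: %s", x$key, x$status))
  if (nrow(x$offending_samples) > 0L)
    cat(" [", paste(sprintf("%s (%s)", x$offending_samples$sample_id,
                            x$offending_samples$reason), collapse = "; "),
        "]", sep = "")
  if (nzchar(x$note)) cat(" - ", x$note, sep = "")
  cat("\n")
  invisible(x)
}

#' Recessive genotype-phenotype concordance of one variant
#'
#' Applies the autosomal-recessive exclusion predicates literally over a
#' genotyped cohort: the variant is `excluded_genotype` iff some affected
#' sample has a non-missing alt-allele count different from 2, or some
#' unaffected sample is homozygous alternate. MISSING calls are ignored
#' and are never grounds for exclusion; if every call is missing the
#' verdict is `uninformative`. Samples genotyped but absent from the
#' phenotype table are treated as unknown (with a warning) and take no
#' part in the test.
#'
#' @param key Variant key (carried into the verdict).
#' @param calls Named integer vector of alt-allele counts (NA = missing).
#' @param phen A [phenotypes()] data.frame.
#' @return A `ConcordanceVerdict`.
#' @export
recessive_concordance <- function(key, calls, phen) {
  status <- stats::setNames(phen$status, phen$sample_id)[names(calls)]
  if (anyNA(status)) {
    warning("no phenotype for sample(s) ",
            paste(names(calls)[is.na(status)], collapse = ", "),
            "; treated as unknown", call. = FALSE)
    status[is.na(status)] <- "unknown"
  }
  if (all(is.na(calls)))
    return(.verdict(key, "uninformative", note = "all calls missing"))
  informative <- !is.na(calls)
  aff_bad <- informative & status == "affected" & calls != 2L
  una_bad <- informative & status == "unaffected" & calls == 2L
  if (any(aff_bad) || any(una_bad)) {
    off <- data.frame(
      sample_id = c(names(calls)[aff_bad], names(calls)[una_bad]),
      reason = c(rep("affected_not_hom_alt", sum(aff_bad)),
                 rep("unaffected_hom_alt", sum(una_bad))),
      stringsAsFactors = FALSE
    )
    return(.verdict(key, "excluded_genotype", off))
  }
  .verdict(key, "retained")
}

#' Concordance screen over a genotyped cohort
#'
#' One [recessive_concordance()] verdict per variant, in CallSet order.
#' Genotype tables transcribed from published base-pair grids do not
#' declare which allele is the alternate; with `check_flip = TRUE`
#' (the default) a variant is excluded only when it is discordant under
#' *both* consistent allele orientations (the declared one and its flip,
#' dosage `2 - g`), so an exclusion never hinges on the transcriber's
#' orientation choice. Offending samples are reported from the declared
#' orientation. Set `check_flip = FALSE` when the alternate allele is
#' known (e.g. calls read from a VCF against a reference).
#'
#' @param x A `CallSet`.
#' @param phen A [phenotypes()] data.frame.
#' @param check_flip Require discordance under both allele orientations.
#' @return List of `ConcordanceVerdict` objects, named by variant key.
#' @export
concordance_screen <- function(x, phen, check_flip = TRUE) {
  out <- lapply(seq_len(n_variants(x)), function(i) {
    key <- x$variants$key[i]
    v <- recessive_concordance(key, x$geno[i, ], phen)
    if (check_flip && v$status == "excluded_genotype") {
      flipped <- recessive_concordance(key, 2L - x$geno[i, ], phen)
      if (flipped$status != "excluded_genotype") {
        v <- .verdict(key, "retained",
                      note = "concordant under the flipped allele orientation")
      }
    }
    v
  })
  stats::setNames(out, x$variants$key)
}

#' Status table of a verdict list
#' @param verdicts List of `ConcordanceVerdict`s.
#' @return data.frame with columns `key`, `status`, `n_offending`, `note`.
#' @export
verdict_table <- function(verdicts) {
  data.frame(
    key = vapply(verdicts, `[[`, "", "key"),
    status = vapply(verdicts, `[[`, "", "status"),
    n_offending = vapply(verdicts,
                         function(v) nrow(v$offending_samples), integer(1)),
    note = vapply(verdicts, `[[`, "", "note"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Lineage-based exclusion of a candidate variant
#'
#' A candidate surviving the genotype screen can still be deprioritized
#' when its carriers occur in parts of the studbook that never interbred
#' with the affected lineage. "Unrelated" is operationalized as graph
#' disconnection: the variant is `excluded_lineage` iff some carrier has
#' no undirected parent-child path to the affected individuals' connected
#' component. An empty carrier set is vacuously retained.
#'
#' @param key Variant key.
#' @param carriers Ids of individuals carrying the variant allele.
#' @param ped A `Pedigree`.
#' @param affected Ids of affected individuals (default from phenotype).
#' @return A `ConcordanceVerdict` with status `retained` or
#'   `excluded_lineage`.
#' @export
lineage_exclusion <- function(key, carriers, ped,
                              affected = affected_ids(ped)) {
  missing <- setdiff(carriers, ped$ind$id)
  if (length(missing) > 0L)
    stop("carrier id(s) not in pedigree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(carriers) == 0L)
    return(.verdict(key, "retained", note = "no carriers observed"))
  comp <- connected_component(ped, affected)
  unrelated <- setdiff(carriers, comp)
  if (length(unrelated) > 0L) {
    off <- data.frame(sample_id = unrelated, reason = "unrelated_carrier",
                      stringsAsFactors = FALSE)
    return(.verdict(key, "excluded_lineage", off,
                    note = "carrier(s) disconnected from the affected lineage"))
  }
  .verdict(key, "retained")
}
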