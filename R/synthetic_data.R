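# Functional-class mix used for background variants: proportions follow
# the class shape of a whole-genome trio call set, where modifier-class
# (non-coding) variants dominate by three orders of magnitude.
.background_class_probs <- c(
  stop_gain = 678, start_stop_loss = 134, splice_donor_acceptor = 2547,
  exon_deletion = 4, frameshift = 3602, rare_amino_acid = 0,
  codon_alteration = 1462, missense = 47534, splice_branch = 0,
  utr_deletion = 0, low_other = 89718, modifier = 22064948
)

.retinal_gene_pool <- c(
  "IQCB1", "CDH23", "DTHD1", "CHD3", "CNGB1", "RBP3", "USH1C",
  "CRX", "CEP290", "AIPL1", "RPE65", "RASGRF1", "CCDC114", "NPHP4",
  "RPGR", "PDE6B"
)

#' Simulation parameters for a synthetic variant cohort
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' a sister-species outgroup removing 41% of trio variants, a 51-sample
#' conspecific panel, and seven decoy candidates that pass the trio filter
#' but fail extended-cohort concordance.
#'
#' @param seed Integer initializer for the random stream.
#' @param n_background Count of background (non-causal, non-decoy)
#'   variants.
#' @param share_outgroup Fraction of background variants also carried by
#'   the outgroup individual.
#' @param share_panel Fraction of background variants also segregating in
#'   the conspecific panel.
#' @param n_panel_samples Panel size.
#' @param n_decoys Number of decoy variants (require the extended
#'   pedigree template).
#' @param pedigree_template `"extended"` (studbook-like, three founder
#'   lineages with one cross) or `"trio"`.
#' @param causal_gene,causal_class Annotation of the seeded causal
#'   variant.
#' @param causal_in_panel Force the causal variant into the panel
#'   (negative control: it is then removed at panel subtraction and
#'   recovery fails).
#' @return List of class `SimulationParams`.
#' @export
simulation_params <- function(seed = 1L,
                              n_background = 2000L,
                              share_outgroup = 0.41,
                              share_panel = 0.50,
                              n_panel_samples = 51L,
                              n_decoys = 7L,
                              pedigree_template = c("extended", "trio"),
                              causal_gene = "IQCB1",
                              causal_class = "frameshift",
                              causal_in_panel = FALSE) {
  pedigree_template <- match.arg(pedigree_template)
  stopifnot(
    share_outgroup >= 0, share_outgroup <= 1,
    share_panel >= 0, share_panel <= 1,
    n_background >= 0, n_decoys >= 0, n_panel_samples >= 1
  )
  impact_tier_of(causal_class)  # validates the label
  structure(
    list(seed = as.integer(seed), n_background = as.integer(n_background),
         share_outgroup = share_outgroup, share_panel = share_panel,
         n_panel_samples = as.integer(n_panel_samples),
         n_decoys = as.integer(n_decoys),
         pedigree_template = pedigree_template,
         causal_gene = causal_gene, causal_class = causal_class,
         causal_in_panel = causal_in_panel),
    class = "SimulationParams"
  )
}

#' Synthetic studbook pedigree
#'
#' A three-lineage captive-population topology: an affected lineage
#' (founder carriers 205 x 208 with affected offspring 235 and 247,
#' carrier and wild-type siblings, and an ungenotyped sibling 209), a
#' second lineage that received the allele through a recent cross
#' (carrier sibling 240 mated into it, leaving ungenotyped kittens
#' 260-262 and 264-266), and an unrelated third lineage (222, 223) never
#' interbred with the affected one. The same topology backs the packaged
#' `studbook_synthetic.ped` fixture.
#'
#' @return A [pedigree()] (no genotypes attached).
#' @export
synthetic_studbook <- function() {
  ped_df <- data.frame(
    id    = c("205","208","209","228","235","236","247","248",
              "229","234","230","233","251",
              "240","258","260","261","262","264","265","266",
              "216","217","222","223"),
    sire  = c(NA,  NA,  "205","205","205","205","205","205",
              NA,  NA,  "229","229","229",
              "205","240","240","240","240","258","258","258",
              NA,  NA,  "216","216"),
    dam   = c(NA,  NA,  "208","208","208","208","208","208",
              NA,  NA,  "234","234","234",
              "208","251","251","251","251","233","233","233",
              NA,  NA,  "217","217"),
    sex   = c("1","2","0","1","1","1","2","2",
              "1","2","1","2","2",
              "1","1","0","0","0","0","0","0",
              "1","2","2","2"),
    status = c("unaffected","unaffected","unknown","unaffected","affected",
               "unaffected","affected","unaffected",
               "unaffected","unaffected","unaffected","unaffected","unaffected",
               "unaffected","unaffected","unknown","unknown","unknown",
               "unknown","unknown","unknown",
               "unknown","unknown","unaffected","unaffected"),
    stringsAsFactors = FALSE
  )
  pedigree(ped_df$id, ped_df$sire, ped_df$dam, ped_df$sex, ped_df$status)
}

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a complete cohort bundle
#'
#' Generates trio, outgroup and panel call sets, an extended genotyped
#' cohort, pedigree, phenotypes, a disease-gene list and a truth record,
#' with the statistical structure the funnel assumes:
#' background variants are drawn on one mock chromosome with independent
#' outgroup/panel membership at the stated fractions and genotypes
#' independent of phenotype (per-variant allele frequency uniform on
#' 0.05-0.5); the causal variant is homozygous-alternate in affecteds,
#' heterozygous in both parents, absent from outgroup and panel, and
#' annotated per `causal_gene`/`causal_class`; decoys satisfy the trio
#' pattern but violate extended-cohort concordance. Identical parameters
#' and seed reproduce the bundle exactly.
#'
#' @param params A [simulation_params()] object.
#' @return Object of class `CohortBundle`: list with `params`,
#'   `bundle_id`, `trio`, `outgroup`, `panel`, `cohort` (CallSets),
#'   `pedigree`, `phenotypes`, `genes`, `trio_ids` (named sire/dam/
#'   affected), `truth` (per-variant category table).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "SimulationParams"))
  if (params$pedigree_template == "trio" && params$n_decoys > 0L)
    stop("decoys require the extended pedigree template: with only a trio ",
         "there is no extended cohort for them to be discordant in",
         call. = FALSE)
  .with_seed(params$seed, .simulate_cohort_impl(params))
}

.simulate_cohort_impl <- function(params) {
  if (params$pedigree_template == "extended") {
    ped <- synthetic_studbook()
    cohort_samples <- c("205","208","209","222","223","228","229","230",
                        "233","234","235","236","240","247","248","251",
                        "258")
    trio_ids <- c(sire = "205", dam = "208", affected = "247")
    affected <- c("235", "247")
  } else {
    ped <- pedigree(
      id = c("SIRE", "DAM", "KIT1"),
      sire = c(NA, NA, "SIRE"), dam = c(NA, NA, "DAM"),
      sex = c("1", "2", "0"),
      status = c("unaffected", "unaffected", "affected")
    )
    cohort_samples <- c("SIRE", "DAM", "KIT1")
    trio_ids <- c(sire = "SIRE", dam = "DAM", affected = "KIT1")
    affected <- "KIT1"
  }
  status <- stats::setNames(ped$ind$status, ped$ind$id)[cohort_samples]
  phen <- phenotypes(cohort_samples, unname(status))
  unaffected <- cohort_samples[status == "unaffected"]
  carriers_by_descent <- intersect(unaffected, unname(trio_ids[c("sire","dam")]))

  n_bg <- params$n_background
  n_total <- n_bg + params$n_decoys + 1L
  pos <- sort(sample.int(100L * n_total + 10000L, n_total))
  category <- c(rep("background", n_bg), rep("decoy", params$n_decoys),
                "causal")

  ref <- sample(c("A", "C", "G", "T"), n_total, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  # the causal lesion is a 2 bp frameshifting deletion
  causal_i <- n_total
  alt[causal_i] <- ref[causal_i]
  ref[causal_i] <- paste0(ref[causal_i], "CT")

  klass <- character(n_total)
  gene <- rep(NA_character_, n_total)
  if (n_bg > 0L) {
    klass[1:n_bg] <- sample(names(.background_class_probs), n_bg,
                            replace = TRUE,
                            prob = .background_class_probs)
    has_gene <- stats::runif(n_bg) < 0.8
    gene[1:n_bg][has_gene] <- sprintf("BGENE%04d",
                                      sample.int(500L, sum(has_gene),
                                                 replace = TRUE))
  }
  decoy_idx <- seq_len(params$n_decoys) + n_bg
  gene_list <- unique(c(ic_norm(params$causal_gene), .retinal_gene_pool))
  if (params$n_decoys > 0L) {
    klass[decoy_idx] <- "missense"
    gene[decoy_idx] <- sample(setdiff(gene_list, ic_norm(params$causal_gene)),
                              params$n_decoys, replace = TRUE)
  }
  klass[causal_i] <- params$causal_class
  gene[causal_i] <- params$causal_gene

  vars <- variant_table("chrS", pos, ref, alt, gene, klass)

  in_outgroup <- c(stats::runif(n_bg) < params$share_outgroup,
                   rep(FALSE, params$n_decoys), FALSE)
  in_panel <- c(stats::runif(n_bg) < params$share_panel,
                rep(FALSE, params$n_decoys), params$causal_in_panel)

  # cohort genotypes
  q <- stats::runif(n_total, 0.05, 0.5)
  geno <- matrix(stats::rbinom(n_total * length(cohort_samples), 2L,
                               rep(q, length(cohort_samples))),
                 nrow = n_total, ncol = length(cohort_samples),
                 dimnames = list(NULL, cohort_samples))
  # causal: recessive-concordant across the whole cohort
  geno[causal_i, ] <- ifelse(cohort_samples %in% affected, 2L,
                             ifelse(cohort_samples %in% carriers_by_descent,
                                    1L,
                                    stats::rbinom(length(cohort_samples),
                                                  1L, 0.3)))
  # decoys: trio pattern intact, discordant elsewhere in the cohort
  other_aff <- setdiff(affected, trio_ids[["affected"]])
  free_unaff <- setdiff(unaffected, unname(trio_ids))
  for (d in decoy_idx) {
    geno[d, ] <- stats::rbinom(length(cohort_samples), 1L, 0.3)
    geno[d, trio_ids[["sire"]]] <- 1L
    geno[d, trio_ids[["dam"]]] <- 1L
    geno[d, trio_ids[["affected"]]] <- 2L
    if (length(other_aff) > 0L && stats::runif(1) < 0.5) {
      geno[d, sample(other_aff, 1L)] <- sample(0:1, 1L)
    } else {
      geno[d, sample(free_unaff, 1L)] <- 2L
    }
  }

  cohort <- callset(vars, cohort_samples, geno)
  trio <- subset_samples(cohort, unname(trio_ids))

  # outgroup: one sister-species individual carrying the shared variants
  og_vars <- vars[in_outgroup, , drop = FALSE]
  outgroup <- callset(
    og_vars, "outgroup1",
    matrix(sample(1:2, nrow(og_vars), replace = TRUE, prob = c(0.6, 0.4)),
           ncol = 1L)
  )

  # conspecific panel: HWE draws, at least one carrier per shared variant
  pn <- params$n_panel_samples
  panel_samples <- sprintf("panel%02d", seq_len(pn))
  pv <- which(in_panel)
  qp <- stats::runif(length(pv), 0.05, 0.5)
  pg <- matrix(stats::rbinom(length(pv) * pn, 2L, rep(qp, pn)),
               nrow = length(pv), ncol = pn)
  if (length(pv) > 0L) {
    none <- rowSums(pg >= 1L) == 0L
    pg[none, 1L] <- 1L
  }
  panel <- callset(vars[pv, , drop = FALSE], panel_samples, pg)

  truth <- data.frame(
    key = vars$key, category = category, gene = vars$gene,
    functional_class = vars$functional_class,
    in_outgroup = in_outgroup, in_panel = in_panel,
    stringsAsFactors = FALSE
  )
  bundle_id <- sprintf("tf_%d_%d_%d_%s", params$seed, params$n_background,
                       params$n_decoys, params$pedigree_template)
  structure(
    list(params = params, bundle_id = bundle_id,
         trio = trio, outgroup = outgroup, panel = panel, cohort = cohort,
         pedigree = ped, phenotypes = phen, genes = gene_list,
         trio_ids = trio_ids, truth = truth),
    class = "CohortBundle"
  )
}

#' @export
print.CohortBundle <- function(x, ...) {
  cat(sprintf(
    "CohortBundle %s: %d variant(s) (%d background, %d decoy, 1 causal),\n  cohort of %d, panel of %d, template '%s'\n",
    x$bundle_id, n_variants(x$cohort),
    sum(x$truth$category == "background"), sum(x$truth$category == "decoy"),
    length(x$cohort$samples), length(x$panel$samples),
    x$params$pedigree_template))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits the file dialects the io module defines: `trio.vcf`,
#' `outgroup.vcf`, `panel.vcf`, `cohort.vcf`, `studbook.ped`,
#' `phenotypes.tsv`, `genes.txt`, `truth.json` and `params.json`.
#' Identical bundles produce byte-identical directories.
#'
#' @param bundle A `CohortBundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(bundle$trio, file.path(dir, "trio.vcf"))
  write_vcf(bundle$outgroup, file.path(dir, "outgroup.vcf"))
  write_vcf(bundle$panel, file.path(dir, "panel.vcf"))
  write_vcf(bundle$cohort, file.path(dir, "cohort.vcf"))
  ind <- bundle$pedigree$ind
  ped_lines <- sprintf("FAM1 %s %s %s %s %s", ind$id,
                       ifelse(is.na(ind$sire), "0", ind$sire),
                       ifelse(is.na(ind$dam), "0", ind$dam),
                       ind$sex,
                       c(affected = "2", unaffected = "1",
                         unknown = "0")[ind$status])
  writeLines(ped_lines, file.path(dir, "studbook.ped"))
  utils::write.table(bundle$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$genes, file.path(dir, "genes.txt"))
  jsonlite::write_json(
    list(bundle_id = bundle$bundle_id, trio_ids = as.list(bundle$trio_ids),
         truth = bundle$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(bundle$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run funnel and concordance screen on a bundle
#'
#' End-to-end pipeline: five-stage funnel on the trio/outgroup/panel call
#' sets, then the recessive concordance screen of the survivors over the
#' extended genotyped cohort.
#'
#' @param bundle A `CohortBundle`.
#' @return List with `bundle_id`, `candidates` (funnel survivors),
#'   `report`, `verdicts`, and `retained_keys` (survivors also retained
#'   by the concordance screen).
#' @export
run_pipeline <- function(bundle) {
  fun <- run_funnel(bundle$trio, bundle$outgroup, bundle$panel,
                    bundle$trio_ids[["sire"]], bundle$trio_ids[["dam"]],
                    bundle$trio_ids[["affected"]], bundle$genes)
  cohort_cand <- subset_variants(bundle$cohort, fun$callset$variants$key)
  verdicts <- concordance_screen(cohort_cand, bundle$phenotypes)
  vt <- verdict_table(verdicts)
  list(bundle_id = bundle$bundle_id,
       candidates = fun$callset, report = fun$report,
       verdicts = verdicts,
       retained_keys = vt$key[vt$status == "retained"])
}

#' Check pipeline output against a bundle's truth record
#'
#' @param result Output of [run_pipeline()].
#' @param bundle The `CohortBundle` the result was computed from.
#' @return List with `causal_recovered` (causal among the retained
#'   survivors), `causal_unique` (it is the only one), `false_positives`
#'   (retained non-causal keys), `decoys_excluded` (all decoys carry an
#'   excluded verdict).
#' @export
truth_check <- function(result, bundle) {
  if (!identical(result$bundle_id, bundle$bundle_id))
    stop("pipeline output and truth record come from different bundles (",
         result$bundle_id, " vs ", bundle$bundle_id, ")", call. = FALSE)
  truth <- bundle$truth
  causal_key <- truth$key[truth$category == "causal"]
  decoy_keys <- truth$key[truth$category == "decoy"]
  vt <- verdict_table(result$verdicts)
  decoy_status <- vt$status[match(decoy_keys, vt$key)]
  list(
    causal_recovered = causal_key %in% result$retained_keys,
    causal_unique = identical(sort(result$retained_keys), sort(causal_key)),
    false_positives = setdiff(result$retained_keys, causal_key),
    decoys_excluded = length(decoy_keys) == 0L ||
      all(!is.na(decoy_status) & decoy_status == "excluded_genotype")
  )
}
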