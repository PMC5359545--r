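test_that("recessive concordance applies the two exclusion predicates literally", {
  phen <- phenotypes(c("aff1", "aff2", "una1", "una2"),
                     c("affected", "affected", "unaffected", "unaffected"))
  # concordant: affecteds hom-alt, unaffecteds carrier/ref
  v <- recessive_concordance("k", c(aff1 = 2L, aff2 = 2L, una1 = 1L,
                                    una2 = 0L), phen)
  expect_equal(v$status, "retained")
  expect_equal(nrow(v$offending_samples), 0L)
  # affected heterozygote is an offender
  v <- recessive_concordance("k", c(aff1 = 2L, aff2 = 1L, una1 = 0L,
                                    una2 = 0L), phen)
  expect_equal(v$status, "excluded_genotype")
  expect_equal(v$offending_samples$sample_id, "aff2")
  expect_equal(v$offending_samples$reason, "affected_not_hom_alt")
  # unaffected homozygote-alternate is an offender
  v <- recessive_concordance("k", c(aff1 = 2L, aff2 = 2L, una1 = 2L,
                                    una2 = 0L), phen)
  expect_equal(v$status, "excluded_genotype")
  expect_equal(v$offending_samples$reason, "unaffected_hom_alt")
  # all calls missing -> uninformative
  v <- recessive_concordance("k", c(aff1 = NA, aff2 = NA, una1 = NA,
                                    una2 = NA), phen)
  expect_equal(v$status, "uninformative")
  # unphenotyped genotyped sample: warned and ignored
  expect_warning(
    v <- recessive_concordance("k", c(aff1 = 2L, ghost = 0L), phen),
    "ghost")
  expect_equal(v$status, "retained")
})

test_that("recessive concordance agrees with a brute-force predicate scan", {
  set.seed(23)
  statuses <- c("affected", "unaffected", "unknown")
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    ids <- paste0("s", seq_len(n))
    status <- sample(statuses, n, replace = TRUE)
    calls <- stats::setNames(sample(c(0:2, NA), n, replace = TRUE), ids)
    got <- recessive_concordance("k", calls, phenotypes(ids, status))
    expect_equal(got$status, oracle_concordance_status(calls, status))
  }
})

test_that("adding a MISSING call never changes a verdict", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    ids <- paste0("s", seq_len(n))
    status <- sample(c("affected", "unaffected"), n, replace = TRUE)
    calls <- stats::setNames(sample(0:2, n, replace = TRUE), ids)
    phen <- phenotypes(c(ids, "extra"), c(status, "affected"))
    base <- recessive_concordance("k", calls, phen)
    with_na <- recessive_concordance("k", c(calls, extra = NA_integer_), phen)
    expect_equal(with_na$status, base$status)
  }
})

test_that("the screen reproduces the published cohort's exclusions and survivors", {
  gt <- read_genotype_table(fx("candidate_variant_genotypes.tsv"))
  verdicts <- concordance_screen(gt$callset, gt$phenotypes)
  vt <- verdict_table(verdicts)
  label <- sub(":.*$", "", vt$key)
  expect_setequal(label[vt$status == "excluded_genotype"],
                  c("CHD3", "CNGB1", "DTHD1_942", "RBP3", "USH1C"))
  expect_setequal(label[vt$status == "retained"],
                  c("IQCB1", "CDH23", "DTHD1_144"))
  # same split without the orientation flip on this table
  vt2 <- verdict_table(concordance_screen(gt$callset, gt$phenotypes,
                                          check_flip = FALSE))
  expect_identical(vt2$status, vt$status)
  # restricted to the causal assay column alone: retained
  iq <- subset_variants(gt$callset, "IQCB1:1:wt:delCT")
  expect_equal(concordance_screen(iq, gt$phenotypes)[[1]]$status, "retained")
  # empty callset -> empty verdict list
  expect_length(concordance_screen(empty_callset("s"), gt$phenotypes), 0L)
})

test_that("discordant-homozygote affecteds are excluded under either allele orientation", {
  # two affecteds homozygous for opposite alleles (dosages 2 and 0): the
  # exclusion cannot hinge on which allele the transcriber called alternate
  phen <- phenotypes(c("a1", "a2", "u1"),
                     c("affected", "affected", "unaffected"))
  calls <- c(a1 = 2L, a2 = 0L, u1 = 1L)
  cs <- make_cs(rbind(calls), samples = names(calls))
  v <- concordance_screen(cs, phen, check_flip = TRUE)[[1]]
  expect_equal(v$status, "excluded_genotype")
  # but a variant discordant only under the declared orientation is kept
  # when the flip explains the data (declared-alt simply mislabelled)
  calls2 <- c(a1 = 0L, a2 = 0L, u1 = 1L)   # flipped: 2,2,1 = concordant
  cs2 <- make_cs(rbind(calls2), samples = names(calls2))
  expect_equal(concordance_screen(cs2, phen)[[1]]$status, "retained")
  expect_equal(concordance_screen(cs2, phen, check_flip = FALSE)[[1]]$status,
               "excluded_genotype")
})

test_that("lineage exclusion flags carriers disconnected from the affected component", {
  ped <- read_ped(fx("studbook_synthetic.ped"))
  gt <- read_genotype_table(fx("candidate_variant_genotypes.tsv"))
  aff <- c("235", "247")
  # cat 223 carries the second DTHD1 assay allele but is unrelated
  k <- "DTHD1_144:1:A:C"
  carriers <- names(which(genotypes_of(gt$callset, k) >= 1))
  v <- lineage_exclusion(k, carriers, ped, aff)
  expect_equal(v$status, "excluded_lineage")
  expect_true("223" %in% v$offending_samples$sample_id)
  expect_true(all(v$offending_samples$reason == "unrelated_carrier"))
  # a parent of an affected is connected: retained
  expect_equal(lineage_exclusion(k, "205", ped, aff)$status, "retained")
  # vacuous retention on an empty carrier set
  expect_equal(lineage_exclusion(k, character(0), ped, aff)$status,
               "retained")
  expect_error(lineage_exclusion(k, "999", ped, aff), "not in pedigree")
})

test_that("genotype screen plus lineage exclusion leaves the causal assay as sole candidate", {
  gt <- read_genotype_table(fx("candidate_variant_genotypes.tsv"))
  ped <- read_ped(fx("studbook_synthetic.ped"))
  vt <- verdict_table(concordance_screen(gt$callset, gt$phenotypes))
  survivors <- vt$key[vt$status == "retained"]
  final <- Filter(function(k) {
    calls <- genotypes_of(gt$callset, k)
    carriers <- names(calls)[!is.na(calls) & calls >= 1]
    lineage_exclusion(k, carriers, ped, c("235", "247"))$status == "retained"
  }, survivors)
  expect_equal(final, "IQCB1:1:wt:delCT")
})
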