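stud <- function() read_ped(fx("studbook_synthetic.ped"))

table1_genotypes <- function() {
  t1 <- read_genotype_table(fx("cohort_screening_genotypes.tsv"))
  calls <- genotypes_of(t1$callset, t1$callset$variants$key[1])
  calls[!is.na(calls)]
}

test_that("pedigree construction validates links, statuses and cycles", {
  expect_error(pedigree(c("a", "a")), "unique")
  expect_error(pedigree("a", sire = "ghost"), "not in pedigree")
  expect_error(pedigree(c("a", "b"), sire = c("b", "a")), "cycle")
  ped <- pedigree(c("p", "q", "r"), sire = c(NA, NA, "p"),
                  dam = c(NA, NA, "q"), status = c("unaffected",
                                                   "unaffected", "affected"))
  expect_equal(affected_ids(ped), "r")
  expect_error(set_known_genotypes(ped, c(z = 1L)), "not in pedigree")
  expect_error(set_known_genotypes(ped, c(p = 5L)), "0:2")
})

test_that("obligate carriers are the unaffected parents of affecteds", {
  ped <- stud()
  expect_setequal(obligate_carriers(ped, "247"), c("205", "208"))
  # two affected full siblings share one parent set, no duplicates
  expect_setequal(obligate_carriers(ped, c("235", "247")), c("205", "208"))
  # affected founder with unknown parents -> empty set
  lone <- pedigree("x", status = "affected")
  expect_length(obligate_carriers(lone, "x"), 0L)
  expect_error(obligate_carriers(ped, "999"), "not in pedigree")
})

test_that("mendelian consistency matches the allele-drawing oracle on all 27 trios", {
  ped <- pedigree(c("s", "d", "k"), sire = c(NA, NA, "s"),
                  dam = c(NA, NA, "d"))
  combos <- expand.grid(s = 0:2, d = 0:2, k = 0:2)
  for (i in seq_len(nrow(combos))) {
    a <- c(s = combos$s[i], d = combos$d[i], k = combos$k[i])
    expect_equal(mendelian_consistent(ped, a),
                 oracle_child_possible(a[["k"]], a[["s"]], a[["d"]]),
                 info = paste(a, collapse = "/"))
  }
  expect_error(mendelian_consistent(ped, c(s = 1L, d = 1L)), "missing")
})

test_that("at-risk enumeration agrees with the naive 3^u oracle on small pedigrees", {
  naive_at_risk <- function(ped) {
    fixed <- ped$known_genotypes
    unknowns <- setdiff(ped$ind$id, names(fixed))
    if (length(unknowns) == 0L) return(character(0))
    grid <- do.call(expand.grid, rep(list(0:2), length(unknowns)))
    names(grid) <- unknowns
    carry <- stats::setNames(rep(FALSE, length(unknowns)), unknowns)
    for (i in seq_len(nrow(grid))) {
      a <- c(fixed, unlist(grid[i, , drop = FALSE]))
      if (mendelian_consistent(ped, a)) {
        carry <- carry | unlist(grid[i, , drop = FALSE]) >= 1
      }
    }
    ped$ind$id[ped$ind$id %in% names(carry)[carry]]
  }
  # child of a known carrier: at risk; child of two hom-ref parents: not
  ped1 <- pedigree(c("s", "d", "k1", "k2"),
                   sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"))
  ped1 <- set_known_genotypes(ped1, c(s = 1L, d = 0L))
  expect_setequal(at_risk_individuals(ped1, assume_outside_founders_wt = FALSE),
                  c("k1", "k2"))
  expect_setequal(at_risk_individuals(ped1, assume_outside_founders_wt = FALSE),
                  naive_at_risk(ped1))
  ped2 <- set_known_genotypes(ped1, c(s = 0L, d = 0L))
  expect_length(at_risk_individuals(ped2, assume_outside_founders_wt = FALSE),
                0L)
  # three-generation case with an ungenotyped middle generation
  ped3 <- pedigree(c("g1", "g2", "m", "f", "c"),
                   sire = c(NA, NA, "g1", NA, "m"),
                   dam = c(NA, NA, "g2", NA, "f"))
  ped3 <- set_known_genotypes(ped3, c(g1 = 2L, g2 = 0L, f = 0L))
  expect_setequal(at_risk_individuals(ped3, assume_outside_founders_wt = FALSE),
                  naive_at_risk(ped3))
  expect_setequal(at_risk_individuals(ped3, assume_outside_founders_wt = FALSE),
                  c("m", "c"))
})

test_that("a known carrier's ungenotyped relatives in the studbook are at risk", {
  ped <- set_known_genotypes(stud(), table1_genotypes())
  expect_setequal(at_risk_individuals(ped),
                  c("209", "260", "261", "262", "264", "265", "266"))
})

test_that("outside founders are fixed wild type by default but not under the sensitivity flag", {
  ped <- set_known_genotypes(stud(), table1_genotypes())
  # lifting the founder prior adds the ungenotyped outside founders
  relaxed <- at_risk_individuals(ped, assume_outside_founders_wt = FALSE)
  expect_true(all(c("209", "260", "266") %in% relaxed))
  expect_true(all(c("216", "217") %in% relaxed))
})

test_that("the enumeration bound is enforced rather than approximated", {
  ids <- paste0("u", 1:25)
  ped <- pedigree(ids, status = "affected")  # 25 unconnected unknowns
  expect_error(at_risk_individuals(ped, assume_outside_founders_wt = FALSE,
                                   max_unknowns = 20L),
               "enumeration")
})

test_that("every obligate carrier carries the allele in every consistent completion", {
  # trio with affected child fixed hom-alt: parents must be 1 or 2 in any
  # Mendelian-consistent assignment
  ped <- pedigree(c("s", "d", "k"), sire = c(NA, NA, "s"),
                  dam = c(NA, NA, "d"),
                  status = c("unaffected", "unaffected", "affected"))
  ped <- set_known_genotypes(ped, c(k = 2L))
  grid <- expand.grid(s = 0:2, d = 0:2)
  for (i in seq_len(nrow(grid))) {
    a <- c(s = grid$s[i], d = grid$d[i], k = 2L)
    if (mendelian_consistent(ped, a)) {
      expect_gte(a[["s"]], 1L)
      expect_gte(a[["d"]], 1L)
    }
  }
  expect_setequal(obligate_carriers(ped), c("s", "d"))
})

test_that("connected components follow undirected parent-child edges", {
  ped <- stud()
  comp <- connected_component(ped, c("235", "247"))
  expect_true(all(c("205", "208", "228", "236", "248") %in% comp))
  expect_false("223" %in% comp)
  # symmetric in seed choice within one component
  expect_setequal(comp, connected_component(ped, "205"))
  expect_setequal(connected_component(ped, "223"),
                  c("216", "217", "222", "223"))
  # singleton founder maps to itself
  lone <- pedigree(c("a", "b", "c"), sire = c(NA, NA, "b"),
                   dam = c(NA, NA, NA))
  expect_equal(connected_component(lone, "a"), "a")
  expect_setequal(connected_component(lone, "b"), c("b", "c"))
  expect_error(connected_component(ped, "999"), "not in pedigree")
})
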