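---
title: "Prioritizing recessive disease variants from a cross-species trio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing recessive disease variants from a cross-species trio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triofunnel)
```

## The problem

A rare, apparently autosomal-recessive disease appears in a small captive
population of an endangered species for which no variant database exists.
Whole-genome sequencing of a trio — the affected offspring and its two
unaffected (hence obligate-carrier) parents — produces tens of millions of
variant calls against a related reference genome. The prioritization
problem is to reduce that list to a handful of testable candidates using
only: the trio's genotypes, variant databases of a closely related
domestic species and a sister-species outgroup, a functional-impact
annotation, a curated disease-gene list, genotypes of an extended cohort,
and the population's studbook pedigree.

`triofunnel` implements this cascade as composable, individually testable
operations, together with a cohort simulator so the entire pipeline can be
exercised and validated without any external data.

## The filter cascade

Let $g_s(v) \in \{0, 1, 2, \mathrm{NA}\}$ be the alternate-allele dosage
of sample $s$ at biallelic variant $v$ (NA is a missing call, distinct
from dosage 0). The funnel applies five set-level filters in order:

1. **Trio sites** — keep $v$ with $g_s(v) \ge 1$ for some trio member $s$.
2. **Outgroup subtraction** — drop $v$ whose key occurs with
   $g(v) \ge 1$ in the sister-species outgroup.
3. **Panel subtraction** — likewise against the conspecific-relative
   panel (e.g. 51 domestic relatives).
4. **Recessive segregation** — keep exactly
   $g_\text{affected}(v) = 2$, $g_\text{sire}(v) = g_\text{dam}(v) = 1$.
5. **Gene-list intersection** — keep variants annotated to a curated
   disease gene (case-insensitive symbol match).

Subtraction is *key-level* sharing — the other cohort carries the same
(chrom, pos, ref, alt) site with at least one alternate allele —
because genotype-identical matching across species is ill-defined.
A missing trio call disqualifies a variant at step 4 rather than being
imputed; this is conservative and can only lose candidates with
incomplete trio data, never admit false ones.

Impact severity uses the four-tier SnpEff-style taxonomy
(HIGH > MODERATE > LOW > MODIFIER) over twelve functional classes;
`low_other` and `modifier` absorb all classes not itemised in the HIGH
and MODERATE groups. `select_by_impact()` is exposed separately from
`run_funnel()` so users can apply the severity cut before or after the
gene intersection; published grids report the gene-list column across
all tiers, so the funnel report does too.

The `FunnelReport` records per-class counts after stages
`trio`, `species_specific` (steps 2+3), `phenotype_segregation` and
`gene_list`. For reports produced by `run_funnel()` these counts are
necessarily non-increasing per class and the constructor enforces that.
Grids transcribed from *effect-level* annotator output (one record per
allele per overlapping isoform) can legitimately violate variant-level
monotonicity, so `read_funnel_counts()` loads pre-filled grids without
the check.

```{r funnel-demo}
b <- simulate_cohort(simulation_params(seed = 1, n_background = 500))
res <- run_pipeline(b)
res$report
truth_check(res, b)
```

## Cohort concordance and lineage exclusion

Funnel survivors are screened against an extended genotyped cohort under
the recessive model. A variant is `excluded_genotype` iff some affected
sample has a non-missing dosage other than 2, or some unaffected sample
is homozygous alternate; missing calls are ignored and can never cause an
exclusion; a variant with no informative calls is `uninformative`.

Published genotype grids print raw base pairs without declaring which
allele is the alternate. The table reader therefore requires each column
header to declare its alleles (`CHD3=A/G`), and `concordance_screen()`
defaults to `check_flip = TRUE`: a variant is excluded only when it is
discordant under **both** consistent orientations (the declared dosages
$g$ and their flip $2-g$), so no exclusion hinges on the transcriber's
choice. On the packaged candidate table the verdicts are identical with
and without the flip. When calls come from a VCF the alternate allele is
known and `check_flip = FALSE` applies the literal predicate.

Candidates that survive the genotype screen can still be deprioritized by
*lineage exclusion*: if some carrier of the allele has no undirected
parent–child path to the affected individuals' connected component, the
allele segregates in a part of the studbook that never interbred with the
affected lineage and is unlikely to be causal. Graph disconnection is the
testable operationalization of "unrelated"; it is deliberately coarse
(a connected carrier in a distant branch still counts as related), which
makes the exclusion conservative.

```{r concordance-demo}
gt <- read_genotype_table(
  system.file("extdata", "candidate_variant_genotypes.tsv",
              package = "triofunnel"))
verdict_table(concordance_screen(gt$callset, gt$phenotypes))
```

## Pedigree analysis

The studbook is modelled as a DAG of parent links. Three operations
support breeding management:

* `obligate_carriers()` — unaffected parents of recessive-affected
  individuals are necessarily heterozygous.
* `mendelian_consistent()` — a full dosage assignment is consistent iff
  every non-founder's dosage is attainable by drawing one allele from
  each parent; an unrecorded parent is unconstrained.
* `at_risk_individuals()` — an ungenotyped individual is *at risk* when
  some Mendelian-consistent completion of the known genotypes gives it at
  least one alternate allele. This is a possibility statement, not a
  carrier probability: the breeding recommendation it supports ("genotype
  before mating") does not need a number, and a numeric posterior would
  require founder allele-frequency assumptions the studbook cannot
  justify.

The at-risk search fixes founders that are not ancestral to any known
carrier or affected individual at homozygous reference — outside
lineages are treated as wild type, matching how such populations are
managed; `assume_outside_founders_wt = FALSE` lifts the prior for
sensitivity analysis. Remaining unknowns are enumerated depth-first over
$3^u$ assignments with parents-before-children ordering and local-trio
pruning, with early exit once every unknown has been seen carrying. The
enumeration refuses more than `max_unknowns = 20` unknowns rather than
approximating; larger studbooks should be subdivided at genotyped
individuals.

The packaged `studbook_synthetic.ped` is a constructed transcription of
a three-lineage captive-population figure (such figures are images, not
machine-readable data): it reproduces every cross-checkable anchor — the
trio, the affected siblings, the carrier and wild-type screening
genotypes, the unrelated carrier lineage, the cross that moved the allele
into a second lineage, and the seven ungenotyped at-risk descendants —
but makes no claim of individual-level fidelity beyond those anchors,
and results that depend on it are fixture-level checks. One discrepancy
in the source material is worth noting: the narrative reports five
heterozygous sighted cats while the genotype table lists six carriers;
the packaged fixtures follow the table.

## Frameshift consequence prediction

For a coding deletion `c.<pos>del<bases>` whose length is not a multiple
of three, the default *immediate-stop* convention places the premature
stop at the codon containing the first deleted base,
$\lceil \mathrm{pos}/3 \rceil$, and reports
`residues_lost = protein_length − stop + 1` when the protein length is
known. This convention is what one must use when the species' transcript
sequence is unavailable; supplying `cds_sequence` switches to translating
the shifted frame to the first downstream stop, which can never precede
the first affected codon but is usually later. The worked example in the
package uses a 597-residue protein so that a stop at codon 428 abolishes
170 residues (428 + 170 − 1 = 597); the orthologous human protein is
commonly given as 598 residues, and the package documents this
reconciliation rather than asserting either length as biological truth.
Without a protein sequence the protein notation degrades from `p.L428*`
to `p.428*` with a notice, since the reference residue letter cannot be
derived from a coordinate alone.

## The simulator: what it does and does not emulate

`simulate_cohort()` generates, from a single seed, the complete input
bundle: trio/outgroup/panel/cohort call sets, pedigree, phenotypes, gene
list and a truth record. Its defaults are the study conditions the
pipeline targets, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_background` | 2000 | large enough for stable stage counts, small enough for fast repeated simulation |
| `share_outgroup` | 0.41 | the fraction of trio variants a single sister-species genome removed in the motivating analysis |
| `share_panel` | 0.50 | not reported for the domestic panel; a realistic mid-range sharing level for a within-lineage panel |
| `n_panel_samples` | 51 | the domestic-relative panel size |
| `n_decoys` | 7 | the number of gene-list missense candidates that survived the trio funnel and had to be eliminated by cohort genotyping |
| allele frequency | U(0.05, 0.5) per variant | simplicity over realism |

Background variants live on one linear mock chromosome with
collision-free uniform positions; outgroup and panel membership are
independent Bernoulli draws at the stated fractions; genotypes of
non-causal variants are Hardy–Weinberg draws independent of phenotype
*and of the pedigree structure*. Functional classes follow a fixed
multinomial dominated by the modifier class, mirroring a genome-wide call
set's shape. The causal variant is a 2-bp deletion, homozygous in
affecteds, heterozygous in both parents, absent from outgroup and panel,
annotated to a gene on the list; decoys reproduce the trio pattern but
are forced discordant in the extended cohort (a non-trio affected
demoted, or an unaffected promoted to homozygous alternate).

What the simulator does **not** model: linkage disequilibrium, shared
ancestry in background genotypes, sequencing or genotyping error,
mutation-rate heterogeneity, structural variants, or realistic genome
coordinates. Consequently, passing end-to-end tests demonstrates the
*logic* of the cascade — set algebra, segregation arithmetic, report
bookkeeping, truth accounting — under the stated statistical structure;
it does not demonstrate robustness to correlated genotypes or annotation
noise in real data. Recovery of the seeded causal variant is guaranteed
by construction whenever the gene pools of background and list are
disjoint; the simulator keeps them disjoint precisely so that the test
isolates pipeline defects rather than sampling luck.

## Numerical and degenerate-input choices

* Missing calls are `NA`, never 0; every filter treats NA as "carries
  nothing" and the segregation filter treats it as disqualifying.
* Multiallelic VCF records are decomposed into one variant per alternate
  allele before any filtering; a `1/2` genotype contributes one copy to
  each decomposed variant. Phase is discarded.
* With several `gene|class` annotation tokens on one record, the
  highest-impact one wins; ties keep the first.
* An empty gene list is an error in `intersect_gene_list()` — it would
  silently empty the funnel.
* Readers reject malformed input naming the offending line or cell; a
  parent id absent from a PED file is an error unless implicit founders
  are explicitly allowed.
* `variant_key()` is `chrom:pos:ref:alt`; `:` is forbidden inside fields,
  which keeps the key injective. Symbolic alleles (`wt`, `delCT`) are
  admitted for assay-table variants that have no sequence context; VCF
  I/O enforces strict A/C/G/T.
* Exit codes of the command-line layer: 0 success, 2 usage error,
  1 runtime failure.

## Problem sizes used by the test suite

The shipped tests run the full cascade on simulated bundles of 300–2000
background variants, repeat end-to-end recovery over 50 seeds, check the
outgroup-sharing fraction at 10,000 variants against a three-standard-
deviation binomial band, and enumerate all 27 trio genotype combinations
and all 9 diploid multiallelic genotypes exhaustively. These sizes give
stable results in seconds on one core.

## Limitations

Beyond the simulator's simplifications above: the package models
biallelic, autosomal, fully penetrant recessive inheritance only — no
X-linkage, de novo dominant models, compound heterozygotes, or reduced
penetrance; the annotator itself is not re-implemented (its output
categories are consumed); lineage exclusion is advisory and depends on
studbook completeness; and at-risk status is qualitative by design.
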