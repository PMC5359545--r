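Package: triofunnel
Title: Trio-Based Cross-Species Variant Prioritization for Recessive Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A filter-cascade pipeline for prioritizing candidate causal
    variants of a recessive Mendelian disease from whole-genome variant
    calls of an affected trio, using subtraction of variants shared with a
    sister-species outgroup and a conspecific-relative panel, SnpEff-style
    impact tiers, intersection with a curated disease-gene list,
    genotype-phenotype concordance screening over an extended genotyped
    cohort, studbook pedigree analysis (obligate carriers, Mendelian
    consistency, at-risk enumeration), and frameshift consequence
    prediction from HGVS coding notation. Includes a synthetic cohort
    simulator with a seeded causal variant and decoys so the whole cascade
    is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
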