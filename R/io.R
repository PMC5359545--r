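ic_norm <- function(x) toupper(trimws(x))

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are skipped; symbols
#' are trimmed, upper-cased and de-duplicated (gene symbols are compared
#' case-insensitively throughout the package).
#'
#' @param path Path to a text file.
#' @return Character vector of unique, case-normalised gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(ic_norm(lines))
}

# -- VCF -----------------------------------------------------------------

# Parse one ANN-style token list ("gene|class" entries, comma separated).
# With several annotations for one record the highest-impact one wins.
.parse_ann <- function(info) {
  m <- regmatches(info, regexpr("ANN=[^;]*", info))
  if (length(m) == 0L) return(list(gene = NA_character_, class = "low_other"))
  toks <- strsplit(sub("^ANN=", "", m), ",", fixed = TRUE)[[1]]
  parts <- strsplit(toks, "|", fixed = TRUE)
  genes <- vapply(parts, function(p) if (length(p) >= 1) trimws(p[[1]]) else NA_character_, "")
  classes <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[[2]]) else "low_other", "")
  classes[!classes %in% functional_classes()] <- "low_other"
  best <- which.min(tier_rank(impact_tier_of(classes)))
  list(gene = if (nzchar(genes[best])) genes[best] else NA_character_,
       class = classes[best])
}

# Decompose a diploid GT string into per-alternate-allele dosages.
# Returns integer vector of length n_alt, or NA vector if any allele is ".".
.gt_dosage <- function(gt, n_alt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(rep(NA_integer_, n_alt))
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".") || length(alleles) == 0L) return(rep(NA_integer_, n_alt))
  idx <- suppressWarnings(as.integer(alleles))
  if (anyNA(idx) || any(idx < 0L) || any(idx > n_alt))
    return(rep(NA_integer_, n_alt))
  vapply(seq_len(n_alt), function(k) sum(idx == k), integer(1))
}

#' Read a VCF into a CallSet
#'
#' Consumes a VCF v4.2 file with a mandatory `GT` FORMAT field. Each record
#' contributes one variant per alternate allele (multiallelic records are
#' decomposed; a `1/2` genotype counts one copy of each alternate). A
#' `./.` genotype becomes a MISSING call, never dosage 0. Functional class
#' and gene symbol are taken from an `ANN=gene|class` INFO token list when
#' present (highest impact wins); unannotated records are `low_other`.
#' Phase separators are accepted and discarded.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A [callset()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path, call. = FALSE)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  gt <- vcf@gt
  if (nrow(fix) == 0L) {
    samp <- character(0)
    if (!is.null(gt) && ncol(gt) > 1L) samp <- colnames(gt)[-1L]
    return(empty_callset(samp))
  }
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample/FORMAT columns; a GT field is required",
         call. = FALSE)
  fmt <- gt[, 1L]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (!all(has_gt))
    stop("VCF record(s) without GT in FORMAT (first at data line ",
         which(!has_gt)[1], ")", call. = FALSE)
  samples <- colnames(gt)[-1L]
  gt_only <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "GT", return.alleles = FALSE)
  )
  gt_only <- matrix(as.character(gt_only), nrow = nrow(fix),
                    dimnames = list(NULL, samples))

  chrom <- c(); pos <- c(); ref <- c(); alt <- c()
  gene <- c(); klass <- c()
  geno_rows <- list()
  for (i in seq_len(nrow(fix))) {
    ref_i <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (is.na(ref_i) || length(alts) == 0L || any(!nzchar(alts)))
      stop("malformed VCF record at data line ", i, call. = FALSE)
    if (grepl("[^ACGTacgt]", ref_i) || any(grepl("[^ACGTacgt]", alts)))
      stop("non-ACGT allele in VCF record at data line ", i, call. = FALSE)
    ann <- .parse_ann(if (is.na(fix[i, "INFO"])) "" else fix[i, "INFO"])
    dos <- vapply(gt_only[i, ], .gt_dosage, integer(length(alts)),
                  n_alt = length(alts))
    dos <- matrix(dos, nrow = length(alts))   # alts x samples
    for (k in seq_along(alts)) {
      chrom <- c(chrom, fix[i, "CHROM"])
      pos <- c(pos, as.integer(fix[i, "POS"]))
      ref <- c(ref, toupper(ref_i))
      alt <- c(alt, toupper(alts[k]))
      gene <- c(gene, ann$gene)
      klass <- c(klass, ann$class)
      geno_rows[[length(geno_rows) + 1L]] <- dos[k, ]
    }
  }
  geno <- do.call(rbind, geno_rows)
  callset(variant_table(chrom, pos, ref, alt, gene, klass), samples, geno)
}

#' Write a CallSet as an uncompressed VCF
#'
#' Inverse of [read_vcf()] for biallelic CallSets: keys, genotypes (with
#' `NA` written as `./.`) and gene/class annotations round-trip exactly.
#' Requires strictly nucleotide alleles.
#'
#' @param x A `CallSet`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  if (n_variants(x) > 0L &&
      (any(grepl("[^ACGT]", v$ref)) || any(grepl("[^ACGT]", v$alt))))
    stop("write_vcf requires nucleotide (A/C/G/T) alleles", call. = FALSE)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotation: gene|functional_class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  body <- character(n_variants(x))
  for (i in seq_len(n_variants(x))) {
    info <- if (is.na(v$gene[i]) && v$functional_class[i] == "low_other") "."
            else paste0("ANN=", ifelse(is.na(v$gene[i]), "", v$gene[i]),
                        "|", v$functional_class[i])
    g <- x$geno[i, ]
    gt <- ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L])
    body[i] <- paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                       "PASS", info, "GT", gt), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# -- PED -----------------------------------------------------------------

#' Read a PLINK-style 6-column pedigree file
#'
#' Columns: family id, individual id, sire id, dam id, sex, phenotype code.
#' `0` marks a missing parent (founder sentinel). Phenotype codes map
#' `2 -> affected`, `1 -> unaffected`, `0`/`-9 -> unknown`. Parent links are
#' checked for cycles; a parent id that never appears as an individual is
#' an error unless `allow_implicit_founders = TRUE`, in which case it is
#' added as an unknown-phenotype founder.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @param allow_implicit_founders Accept parent ids absent from column 2.
#' @return A [pedigree()].
#' @export
read_ped <- function(path, allow_implicit_founders = FALSE) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L)
    stop("PED file must have exactly 6 columns, found ", ncol(ped),
         call. = FALSE)
  names(ped) <- c("family_id", "individual_id", "sire_id", "dam_id",
                  "sex", "phenotype_code")
  own_parent <- ped$individual_id == ped$sire_id |
                ped$individual_id == ped$dam_id
  if (any(own_parent))
    stop("individual listed as its own parent at line ",
         which(own_parent)[1], ": ", ped$individual_id[own_parent][1],
         call. = FALSE)
  parents <- setdiff(c(ped$sire_id, ped$dam_id), c("0", ped$individual_id))
  if (length(parents) > 0L) {
    if (!allow_implicit_founders)
      stop("parent id(s) absent from file: ", paste(parents, collapse = ", "),
           " (set allow_implicit_founders = TRUE to add them as founders)",
           call. = FALSE)
    ped <- rbind(ped, data.frame(
      family_id = ped$family_id[1], individual_id = parents,
      sire_id = "0", dam_id = "0", sex = "0", phenotype_code = "0",
      stringsAsFactors = FALSE))
  }
  status <- c("2" = "affected", "1" = "unaffected",
              "0" = "unknown", "-9" = "unknown")[ped$phenotype_code]
  status[is.na(status)] <- "unknown"
  pedigree(
    id = ped$individual_id,
    sire = ifelse(ped$sire_id == "0", NA_character_, ped$sire_id),
    dam = ifelse(ped$dam_id == "0", NA_character_, ped$dam_id),
    sex = ped$sex,
    status = unname(status)
  )
}

# -- Genotype table ------------------------------------------------------

# Parse one genotype cell against declared ref/alt alleles.
# Accepts "X/Y", a two-base pair like "AG", a bare allele (homozygous
# shorthand), and "/" or "" for a missing call.
.parse_cell <- function(cell, ref, alt, where) {
  cell <- trimws(cell)
  if (cell %in% c("/", "", ".", "./.", NA_character_)) return(NA_integer_)
  if (grepl("/", cell, fixed = TRUE)) {
    alleles <- strsplit(cell, "/", fixed = TRUE)[[1]]
    alleles <- alleles[nzchar(alleles)]
  } else if (nchar(cell) == 2L && nchar(ref) == 1L && nchar(alt) == 1L) {
    alleles <- strsplit(cell, "")[[1]]
  } else {
    alleles <- cell
  }
  if (length(alleles) == 1L) alleles <- rep(alleles, 2L)  # "wt" == "wt/wt"
  if (length(alleles) != 2L || !all(alleles %in% c(ref, alt)))
    stop("allele not in {", ref, ", ", alt, "} in cell ", where,
         call. = FALSE)
  sum(alleles == alt)
}

#' Read a cohort genotype table (TSV with declared alleles)
#'
#' The table has columns `sample_id`, `phenotype`, then one column per
#' variant whose header declares the column's allele orientation as
#' `LABEL=ref/alt` (e.g. `IQCB1=wt/delCT`, `CHD3=A/G`). Cells hold allele
#' pairs (`wt/delCT`, `AG`, a bare allele as homozygous shorthand) and
#' `"/"` for a failed sample (MISSING). Variant labels are opaque; they are
#' used as both sequence name and gene symbol of the resulting variants,
#' with a trailing `_<digits>` suffix stripped for the gene symbol so that
#' several assays in one gene share it.
#'
#' @param path Path to the TSV file.
#' @return List with elements `callset` (a [callset()], one variant per
#'   column, placeholder position 1) and `phenotypes` (a [phenotypes()]
#'   table).
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (!all(c("sample_id", "phenotype") %in% names(tab)))
    stop("genotype table needs 'sample_id' and 'phenotype' columns",
         call. = FALSE)
  vcols <- setdiff(names(tab), c("sample_id", "phenotype"))
  if (length(vcols) == 0L)
    stop("genotype table has no variant columns", call. = FALSE)
  spec <- regmatches(vcols, regexec("^([^=]+)=([^/]+)/(.+)$", vcols))
  bad <- vcols[vapply(spec, length, integer(1)) != 4L]
  if (length(bad) > 0L)
    stop("variant column header(s) must declare alleles as LABEL=ref/alt: ",
         paste(bad, collapse = ", "), call. = FALSE)
  labels <- vapply(spec, `[[`, "", 2L)
  refs <- vapply(spec, `[[`, "", 3L)
  alts <- vapply(spec, `[[`, "", 4L)

  samples <- tab$sample_id
  geno <- matrix(NA_integer_, nrow = length(vcols), ncol = length(samples))
  for (j in seq_along(vcols)) {
    for (s in seq_along(samples)) {
      geno[j, s] <- .parse_cell(
        tab[[vcols[j]]][s], refs[j], alts[j],
        where = paste0("(sample ", samples[s], ", column ", labels[j], ")"))
    }
  }
  status <- .phenotype_label(tab$phenotype)
  vars <- variant_table(
    chrom = labels, pos = 1L, ref = refs, alt = alts,
    gene = ic_norm(sub("_[0-9]+$", "", labels)),
    functional_class = "low_other"
  )
  list(callset = callset(vars, samples, geno),
       phenotypes = phenotypes(samples, status))
}

# Free-text phenotype labels to canonical statuses. "Normal (parent of
# affected)" style annotations must not be mistaken for affected, so the
# unaffected vocabulary is checked first.
.phenotype_label <- function(x) {
  x0 <- tolower(trimws(x))
  ifelse(grepl("^(normal|unaffected|control|sighted)", x0), "unaffected",
         ifelse(grepl("affected", x0), "affected", "unknown"))
}
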