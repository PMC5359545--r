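#' Construct a pedigree
#'
#' Individuals with optional sire/dam links (NA = unknown/founder side),
#' sex (carried but unused: the inheritance model is autosomal) and
#' phenotype status, plus an optional partial genotype assignment
#' (alt-allele counts for a single biallelic locus). Parent links are
#' checked for cycles and for dangling ids.
#'
#' @param id Character vector of unique individual ids.
#' @param sire,dam Parent ids (`NA` for unknown).
#' @param sex Sex codes, free-form (`"1"`/`"2"`/`"0"` in PED files).
#' @param status Phenotype status per individual
#'   (`affected`/`unaffected`/`unknown`).
#' @param known_genotypes Named integer vector (names = ids, values in
#'   0:2) of known alt-allele counts.
#' @return Object of class `Pedigree`: a list with a data.frame `ind` and
#'   the `known_genotypes` vector.
#' @export
pedigree <- function(id, sire = NA_character_, dam = NA_character_,
                     sex = "0", status = "unknown",
                     known_genotypes = integer(0)) {
  n <- length(id)
  ind <- data.frame(
    id = as.character(id),
    sire = rep_len(as.character(sire), n),
    dam = rep_len(as.character(dam), n),
    sex = rep_len(as.character(sex), n),
    status = rep_len(as.character(status), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ind$id))
    stop("individual ids must be unique", call. = FALSE)
  bad_status <- setdiff(unique(ind$status),
                        c("affected", "unaffected", "unknown"))
  if (length(bad_status) > 0L)
    stop("invalid phenotype status: ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  dangling <- setdiff(stats::na.omit(c(ind$sire, ind$dam)), ind$id)
  if (length(dangling) > 0L)
    stop("parent id(s) not in pedigree: ", paste(dangling, collapse = ", "),
         call. = FALSE)
  ped <- structure(list(ind = ind, known_genotypes = integer(0)),
                   class = "Pedigree")
  g <- .parent_graph(ped, directed = TRUE)
  if (igraph::vcount(g) > 0L && !igraph::is_dag(g))
    stop("pedigree parent links contain a cycle (an individual is its own ",
         "ancestor)", call. = FALSE)
  set_known_genotypes(ped, known_genotypes)
}

.parent_graph <- function(ped, directed = FALSE) {
  ind <- ped$ind
  edges <- rbind(
    data.frame(from = ind$sire, to = ind$id, stringsAsFactors = FALSE),
    data.frame(from = ind$dam, to = ind$id, stringsAsFactors = FALSE)
  )
  edges <- edges[!is.na(edges$from), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = directed,
                                vertices = data.frame(name = ind$id))
}

#' Attach known single-locus genotypes to a pedigree
#' @param ped A `Pedigree`.
#' @param known_genotypes Named integer vector (values in 0:2).
#' @return The updated `Pedigree`.
#' @export
set_known_genotypes <- function(ped, known_genotypes) {
  kg <- known_genotypes[!is.na(known_genotypes)]
  if (length(kg) > 0L) {
    if (is.null(names(kg)) || any(!nzchar(names(kg))))
      stop("known_genotypes must be a named vector", call. = FALSE)
    outside <- setdiff(names(kg), ped$ind$id)
    if (length(outside) > 0L)
      stop("known genotype(s) for id(s) not in pedigree: ",
           paste(outside, collapse = ", "), call. = FALSE)
    if (!all(kg %in% 0:2))
      stop("known genotypes must be alt-allele counts in 0:2", call. = FALSE)
  }
  ped$known_genotypes <- stats::setNames(as.integer(kg), names(kg))
  ped
}

#' @export
print.Pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individual(s), %d founder(s), %d affected, %d genotyped\n",
              nrow(x$ind),
              sum(is.na(x$ind$sire) & is.na(x$ind$dam)),
              sum(x$ind$status == "affected"),
              length(x$known_genotypes)))
  invisible(x)
}

#' Affected individuals of a pedigree
#' @param ped A `Pedigree`.
#' @return Character vector of ids.
#' @export
affected_ids <- function(ped) ped$ind$id[ped$ind$status == "affected"]

#' Obligate carriers under a recessive model
#'
#' Every unaffected parent of a recessive-affected individual must carry
#' one copy of the causal allele. Returns all parents of the given
#' affected individuals that are not themselves affected.
#'
#' @param ped A `Pedigree`.
#' @param affected Ids of affected individuals (default: from phenotype).
#' @return Character vector of ids (no duplicates).
#' @export
obligate_carriers <- function(ped, affected = affected_ids(ped)) {
  missing <- setdiff(affected, ped$ind$id)
  if (length(missing) > 0L)
    stop("affected id(s) not in pedigree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- ped$ind[ped$ind$id %in% affected, , drop = FALSE]
  parents <- unique(stats::na.omit(c(rows$sire, rows$dam)))
  aff <- ped$ind$id[ped$ind$status == "affected"]
  setdiff(parents, aff)
}

#' Undirected connected component containing a set of individuals
#'
#' Reachability via undirected parent-child edges; the operational notion
#' of "related" used for lineage-based candidate exclusion.
#'
#' @param ped A `Pedigree`.
#' @param seeds Ids to start from.
#' @return Character vector of all ids reachable from any seed (including
#'   the seeds).
#' @export
connected_component <- function(ped, seeds) {
  missing <- setdiff(seeds, ped$ind$id)
  if (length(missing) > 0L)
    stop("seed id(s) not in pedigree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(seeds) == 0L) return(character(0))
  g <- .parent_graph(ped, directed = FALSE)
  comp <- igraph::components(g)
  member <- comp$membership[seeds]
  names(comp$membership)[comp$membership %in% member]
}

# Possible offspring dosages from parental dosages: one allele drawn from
# each parent. An NA parent (unknown) is unconstrained.
.allele_draws <- function(g) {
  if (is.na(g)) return(0:1)
  switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
}

.child_possible <- function(child, sire_g, dam_g) {
  child %in% outer(.allele_draws(sire_g), .allele_draws(dam_g), `+`)
}

#' Mendelian consistency of a full genotype assignment
#'
#' @param ped A `Pedigree`.
#' @param assignment Named integer vector covering every individual
#'   (values in 0:2).
#' @return `TRUE` iff every non-founder's alt-allele count is attainable
#'   by drawing one allele from each parent's genotype. An individual with
#'   a single recorded parent is constrained by that parent only.
#' @export
mendelian_consistent <- function(ped, assignment) {
  missing <- setdiff(ped$ind$id, names(assignment))
  if (length(missing) > 0L)
    stop("assignment must cover every individual; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(ped$ind))) {
    sire <- ped$ind$sire[i]; dam <- ped$ind$dam[i]
    if (is.na(sire) && is.na(dam)) next
    ok <- .child_possible(
      assignment[[ped$ind$id[i]]],
      if (is.na(sire)) NA_integer_ else assignment[[sire]],
      if (is.na(dam)) NA_integer_ else assignment[[dam]]
    )
    if (!ok) return(FALSE)
  }
  TRUE
}

# Founders with no descendant (nor themselves) known to carry the allele
# or affected: fixed hom-ref under the default founder prior.
.outside_founders <- function(ped) {
  ind <- ped$ind
  founders <- ind$id[is.na(ind$sire) & is.na(ind$dam)]
  carriers <- union(names(ped$known_genotypes)[ped$known_genotypes >= 1L],
                    affected_ids(ped))
  if (length(carriers) == 0L) return(founders)
  g <- .parent_graph(ped, directed = TRUE)
  keep <- vapply(founders, function(f) {
    desc <- names(igraph::subcomponent(g, f, mode = "out"))
    !any(desc %in% carriers)
  }, logical(1))
  founders[keep]
}

#' Individuals at risk of carrying the allele
#'
#' An ungenotyped individual is "at risk" when some Mendelian-consistent
#' completion of the pedigree's partial genotype assignment gives it at
#' least one alternate allele - a possibility statement, not a numeric
#' carrier probability. Under the default founder prior, founders that are
#' not ancestral to any known carrier or affected individual are fixed
#' homozygous reference (outside lineages are treated as wild type);
#' `assume_outside_founders_wt = FALSE` lifts this for sensitivity
#' analysis. The search enumerates assignments of the unknown genotypes
#' depth-first with pruning and refuses pedigrees with more than
#' `max_unknowns` unknowns rather than approximating.
#'
#' @param ped A `Pedigree` with `known_genotypes` set.
#' @param assume_outside_founders_wt Fix outside founders to dosage 0.
#' @param max_unknowns Enumeration bound on the number of unknown
#'   genotypes.
#' @return Character vector of at-risk ids, in pedigree order.
#' @export
at_risk_individuals <- function(ped, assume_outside_founders_wt = TRUE,
                                max_unknowns = 20L) {
  fixed <- ped$known_genotypes
  if (assume_outside_founders_wt) {
    outside <- setdiff(.outside_founders(ped), names(fixed))
    fixed <- c(fixed, stats::setNames(rep(0L, length(outside)), outside))
  }
  ids <- ped$ind$id
  unknowns <- setdiff(ids, names(fixed))
  if (length(unknowns) > max_unknowns)
    stop(length(unknowns), " unknown genotypes exceed the enumeration ",
         "bound of ", max_unknowns, "; subdivide the pedigree or raise ",
         "max_unknowns", call. = FALSE)
  if (length(unknowns) == 0L) return(character(0))

  # order unknowns parents-before-children so pruning bites early
  g <- .parent_graph(ped, directed = TRUE)
  topo <- names(igraph::topo_sort(g, mode = "out"))
  unknowns <- topo[topo %in% unknowns]

  assign_env <- new.env(parent = emptyenv())
  for (nm in names(fixed)) assign(nm, fixed[[nm]], envir = assign_env)
  can_carry <- stats::setNames(rep(FALSE, length(unknowns)), unknowns)
  row_of <- stats::setNames(seq_along(ids), ids)
  ind <- ped$ind

  consistent_so_far <- function(id) {
    # check the trio constraint of `id` and of its children whose other
    # parent is already assigned (or unknown -> unconstrained yet)
    check_one <- function(i) {
      sire <- ind$sire[i]; dam <- ind$dam[i]
      if (is.na(sire) && is.na(dam)) return(TRUE)
      cg <- get0(ind$id[i], envir = assign_env, ifnotfound = NA_integer_)
      if (is.na(cg)) return(TRUE)
      sg <- if (is.na(sire)) NA_integer_ else
        get0(sire, envir = assign_env, ifnotfound = NA_integer_)
      dg <- if (is.na(dam)) NA_integer_ else
        get0(dam, envir = assign_env, ifnotfound = NA_integer_)
      # with an unassigned parent the constraint cannot fail yet unless the
      # other parent already forbids the child outright
      .child_possible(cg, sg, dg)
    }
    i <- row_of[[id]]
    if (!check_one(i)) return(FALSE)
    kids <- which(ind$sire == id | ind$dam == id)
    all(vapply(kids, check_one, logical(1)))
  }

  recurse <- function(k) {
    if (k > length(unknowns)) {
      for (u in unknowns) {
        if (get(u, envir = assign_env) >= 1L) can_carry[[u]] <<- TRUE
      }
      return(invisible())
    }
    if (all(can_carry)) return(invisible())  # nothing left to learn
    u <- unknowns[k]
    for (val in 0:2) {
      assign(u, val, envir = assign_env)
      if (consistent_so_far(u)) recurse(k + 1L)
    }
    rm(list = u, envir = assign_env)
    invisible()
  }
  recurse(1L)
  ids[ids %in% names(can_carry)[can_carry]]
}
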