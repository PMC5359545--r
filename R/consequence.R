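#' Parse HGVS coding deletion notation
#'
#' Supports the deletion subset of HGVS c. notation: `c.<pos>del<bases>`
#' and the equivalent ranged form `c.<start>_<end>del<bases>`. Other
#' notation kinds (substitutions, insertions, duplications) are rejected
#' as unsupported.
#'
#' @param notation A single string, e.g. `"c.1282delCT"`.
#' @return List with `cds_position` (1-based coding nucleotide index of
#'   the first deleted base), `deleted_bases`, `deleted_length`.
#' @export
parse_hgvs_c <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L)
  notation <- trimws(notation)
  m <- regexec("^c\\.([0-9]+)(?:_([0-9]+))?del([ACGT]+)$", notation)
  hit <- regmatches(notation, m)[[1]]
  if (length(hit) == 0L) {
    if (grepl("^c\\.", notation))
      stop("unsupported HGVS c. notation (only deletions of the form ",
           "c.<pos>del<bases> are handled): ", notation, call. = FALSE)
    stop("not HGVS c. notation: ", notation, call. = FALSE)
  }
  pos <- as.integer(hit[2])
  bases <- hit[4]
  if (nzchar(hit[3])) {
    end <- as.integer(hit[3])
    if (end - pos + 1L != nchar(bases))
      stop("deleted range ", pos, "_", end, " does not match ",
           nchar(bases), " deleted base(s) in ", notation, call. = FALSE)
  }
  list(cds_position = pos, deleted_bases = bases,
       deleted_length = nchar(bases))
}

#' Codon number of a coding nucleotide position
#'
#' `ceiling(cds_position / 3)`: positions 1-3 fall in codon 1, and so on.
#'
#' @param cds_position 1-based coding position(s), integer.
#' @return 1-based codon number(s).
#' @export
codon_index <- function(cds_position) {
  cds_position <- as.integer(cds_position)
  if (anyNA(cds_position) || any(cds_position < 1L))
    stop("cds_position must be a positive integer", call. = FALSE)
  as.integer(ceiling(cds_position / 3))
}

#' Predict the protein consequence of a coding frameshift deletion
#'
#' By default the premature stop is placed at the codon containing the
#' first deleted base (`codon_index(cds_position)`) - the immediate-stop
#' convention used when the transcript sequence is unavailable. When the
#' coding sequence is supplied, the shifted reading frame is instead
#' translated to the first downstream stop codon; that stop can never lie
#' before the first affected codon. When the protein length is known the
#' number of wild-type residues abolished is reported
#' (`residues_lost = protein_length - stop_codon_index + 1`).
#'
#' @param cds_position 1-based coding index of the first deleted base.
#' @param deleted Deleted bases (string) or the deletion length (integer).
#'   Lengths that are multiples of 3 are in-frame and rejected unless
#'   `allow_in_frame = TRUE`.
#' @param protein_length Wild-type protein length in residues, optional.
#' @param cds_sequence Wild-type coding sequence (A/C/G/T string including
#'   the stop codon, length a multiple of 3), optional; switches on
#'   sequence-scan stop placement.
#' @param protein_sequence Wild-type protein sequence (one-letter),
#'   optional; supplies the reference residue letter for the p. notation.
#'   Without it the notation degrades to the `p.<codon>*` form.
#' @param allow_in_frame Permit in-frame deletion lengths.
#' @return Object of class `ProteinConsequence`: list with
#'   `cds_position`, `deleted_length`, `stop_codon_index`,
#'   `residues_lost` (NA when the protein length is unknown), `hgvs_c`,
#'   `hgvs_p`.
#' @export
frameshift_consequence <- function(cds_position, deleted,
                                   protein_length = NULL,
                                   cds_sequence = NULL,
                                   protein_sequence = NULL,
                                   allow_in_frame = FALSE) {
  cds_position <- as.integer(cds_position)
  stopifnot(length(cds_position) == 1L, cds_position >= 1L)
  if (is.character(deleted)) {
    deleted_bases <- toupper(deleted)
    deleted_length <- nchar(deleted_bases)
  } else {
    deleted_bases <- NULL
    deleted_length <- as.integer(deleted)
  }
  if (deleted_length < 1L)
    stop("deletion length must be >= 1", call. = FALSE)
  if (deleted_length %% 3L == 0L && !allow_in_frame)
    stop("deletion of ", deleted_length, " base(s) is in-frame, not a ",
         "frameshift; set allow_in_frame = TRUE to override", call. = FALSE)
  if (!is.null(protein_sequence) && is.null(protein_length))
    protein_length <- nchar(protein_sequence)
  if (!is.null(protein_length) && cds_position > 3L * protein_length)
    stop("cds_position ", cds_position, " lies beyond the coding region ",
         "of a ", protein_length, "-residue protein", call. = FALSE)

  stop_idx <- codon_index(cds_position)
  if (!is.null(cds_sequence))
    stop_idx <- .scan_shifted_stop(cds_sequence, cds_position,
                                   deleted_length)

  residues_lost <- if (is.null(protein_length)) NA_integer_ else
    protein_length - stop_idx + 1L
  if (!is.na(residues_lost) && residues_lost < 0L)
    residues_lost <- 0L

  residue <- NULL
  if (!is.null(protein_sequence) && stop_idx <= nchar(protein_sequence))
    residue <- substr(protein_sequence, stop_idx, stop_idx)
  hgvs_p <- if (is.null(residue)) {
    message("reference residue unknown (no protein sequence supplied); ",
            "writing p.", stop_idx, "* form")
    sprintf("p.%d*", stop_idx)
  } else {
    sprintf("p.%s%d*", residue, stop_idx)
  }
  hgvs_c <- if (!is.null(deleted_bases))
    sprintf("c.%ddel%s", cds_position, deleted_bases) else NA_character_

  structure(
    list(cds_position = cds_position, deleted_length = deleted_length,
         stop_codon_index = stop_idx, residues_lost = residues_lost,
         hgvs_c = hgvs_c, hgvs_p = hgvs_p),
    class = "ProteinConsequence"
  )
}

#' @export
print.ProteinConsequence <- function(x, ...) {
  cat(sprintf("%s -> %s (premature stop at codon %d%s)\n",
              ifelse(is.na(x$hgvs_c),
                     sprintf("c.%d del%d", x$cds_position, x$deleted_length),
                     x$hgvs_c),
              x$hgvs_p, x$stop_codon_index,
              ifelse(is.na(x$residues_lost), "",
                     sprintf("; %d residue(s) lost", x$residues_lost))))
  invisible(x)
}

# Translate the frame-shifted sequence and return the codon index of the
# first stop at or after the first affected codon.
.scan_shifted_stop <- function(cds_sequence, cds_position, deleted_length) {
  cds_sequence <- toupper(gsub("[[:space:]]", "", cds_sequence))
  if (grepl("[^ACGT]", cds_sequence))
    stop("cds_sequence must contain only A/C/G/T", call. = FALSE)
  if (cds_position + deleted_length - 1L > nchar(cds_sequence))
    stop("deletion extends beyond the supplied coding sequence",
         call. = FALSE)
  mutated <- paste0(substr(cds_sequence, 1L, cds_position - 1L),
                    substr(cds_sequence, cds_position + deleted_length,
                           nchar(cds_sequence)))
  usable <- 3L * (nchar(mutated) %/% 3L)
  if (usable == 0L)
    stop("mutated coding sequence shorter than one codon", call. = FALSE)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mutated, 1L, usable)),
    no.init.codon = TRUE
  ))
  stops <- which(strsplit(aa, "")[[1]] == "*")
  first_affected <- codon_index(cds_position)
  stops <- stops[stops >= first_affected]
  if (length(stops) == 0L)
    stop("no stop codon downstream of the frameshift within the supplied ",
         "coding sequence", call. = FALSE)
  stops[1L]
}
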