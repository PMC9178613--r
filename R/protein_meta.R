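# Average (not monoisotopic) residue masses: melting-diagram hydration ratios
# are bulk mass quantities, so bulk isotopic averages are the right scale.
.RESIDUE_MASSES <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.0153

#' Average residue masses
#'
#' Named vector of average masses (g/mol) of the 20 canonical amino-acid
#' residues (i.e. amino acid minus one water), as used for protein molar
#' masses throughout the package.
#'
#' @return Named numeric vector of length 20.
#' @export
residue_masses <- function() .RESIDUE_MASSES

#' Protein sequence metadata
#'
#' Builds the sequence-derived constants used by the hydration conversions:
#' the residue count `a` and the average molar mass
#' `M_r = sum of residue masses + one water`.
#'
#' @param sequence amino-acid sequence, 1-letter code, 20 canonical residues
#'   only (case-insensitive).
#' @param name free-text identifier.
#' @return An object of class `"protein_info"` with fields `name`,
#'   `sequence`, `a` (residue count) and `M_r` (g/mol).
#' @examples
#' protein_info("GG")$M_r  # 132.12
#' @export
protein_info <- function(sequence, name = "") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("`sequence` must be a single string")
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty protein sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(.RESIDUE_MASSES))
  if (length(bad))
    stop(sprintf("non-canonical residue letter '%s' at position %d",
                 chars[bad[1]], bad[1]))
  structure(list(
    name = as.character(name),
    sequence = sequence,
    a = length(chars),
    M_r = sum(.RESIDUE_MASSES[chars]) + .WATER_MASS
  ), class = "protein_info")
}

#' @export
print.protein_info <- function(x, ...) {
  cat(sprintf("Protein '%s': %d residues, M_r = %.2f g/mol\n",
              x$name, x$a, x$M_r))
  invisible(x)
}

#' Read a protein sequence from a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file and returns the metadata of one
#' record: the first by default, or the first whose header contains `id`.
#'
#' @param path path to a FASTA file.
#' @param id optional substring selecting a record by its header.
#' @return A [protein_info()] object; the FASTA description becomes `name`.
#' @examples
#' fa <- system.file("extdata", "alpha_synuclein_wt.fasta",
#'                   package = "hydromelt")
#' read_fasta(fa)  # 140 residues, M_r = 14460.2
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readAAStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  i <- 1L
  if (!is.null(id)) {
    hit <- grep(id, names(recs), fixed = TRUE)
    if (!length(hit)) stop("no FASTA record matching id '", id, "'")
    i <- hit[1L]
  }
  protein_info(as.character(recs[[i]]), name = names(recs)[i])
}

#' Write a protein sequence to a FASTA file
#'
#' @param p a [protein_info()] object.
#' @param path output path.
#' @param width line-wrap width for the sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(p, path, width = 60L) {
  if (!inherits(p, "protein_info")) stop("`p` must be a protein_info object")
  x <- Biostrings::AAStringSet(p$sequence)
  names(x) <- if (nzchar(p$name)) p$name else "protein"
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Apply a point mutation
#'
#' Applies a substitution given as a standard mutation code such as `"A30P"`
#' (reference residue, 1-based position, replacement residue).  The reference
#' residue is checked against the sequence; the molar mass shifts by exactly
#' the residue-mass difference.
#'
#' @param p a [protein_info()] object.
#' @param code mutation code, e.g. `"A30P"` or `"E46K"`.
#' @return A new [protein_info()] with the substitution applied; `name` gains
#'   a `" <code>"` suffix.
#' @examples
#' wt <- protein_info("GAG", "toy")
#' apply_mutation(wt, "A2P")$M_r - wt$M_r  # Pro minus Ala = 26.04
#' @export
apply_mutation <- function(p, code) {
  if (!inherits(p, "protein_info")) stop("`p` must be a protein_info object")
  m <- regmatches(code, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", code))[[1]]
  if (length(m) != 4L)
    stop("mutation code must look like 'A30P', got '", code, "'")
  ref <- toupper(m[2]); pos <- as.integer(m[3]); new <- toupper(m[4])
  if (!new %in% names(.RESIDUE_MASSES))
    stop("replacement residue '", new, "' is not a canonical amino acid")
  if (pos < 1L || pos > p$a)
    stop(sprintf("position %d out of range 1..%d", pos, p$a))
  found <- substr(p$sequence, pos, pos)
  if (found != ref)
    stop(sprintf("reference mismatch at position %d: code says %s, sequence has %s",
                 pos, ref, found))
  seq2 <- p$sequence
  substr(seq2, pos, pos) <- new
  out <- protein_info(seq2, name = paste(p$name, toupper(code)))
  out
}
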