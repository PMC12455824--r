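# IUPAC degenerate nucleotide algebra: membership, expansion, degeneracy,
# reverse complement. All sequences are DNA, 5'->3', upper-case.

# canonical 15-letter code table, taken from Biostrings so the package
# shares one source of truth with its FASTA I/O layer
.iupac_sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)

.iupac_codes <- names(.iupac_sets)

#' Validate and normalise a degenerate DNA sequence
#'
#' Upper-cases the input and checks every character against the 15-letter
#' IUPAC nucleotide alphabet (A, C, G, T, R, Y, M, K, S, W, B, D, H, V, N).
#' RNA (`U`), gap characters and anything else are rejected with an error
#' naming the offending character and its position; alignment-derived
#' strings must be de-gapped by the caller.
#'
#' @param x single character string, read 5'->3'.
#' @param what label used in error messages (e.g. `"primer"`).
#' @return The normalised (upper-case) sequence string.
#' @examples
#' as_degenerate("atcaaYaag")
#' @export
as_degenerate <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) < 1L) {
    stop(what, " must have length >= 1", call. = FALSE)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .iupac_codes)
  if (length(bad)) {
    stop(
      "invalid IUPAC nucleotide code '", chars[bad[1]], "' at position ",
      bad[1], " of ", what,
      call. = FALSE
    )
  }
  x
}

#' Nucleotide set denoted by an IUPAC code
#'
#' @param code single IUPAC nucleotide character (case-insensitive).
#' @return Character vector of the concrete bases the code denotes
#'   (1 to 4 of A, C, G, T).
#' @examples
#' iupac_code_set("Y") # C, T
#' iupac_code_set("N") # A, C, G, T
#' @export
iupac_code_set <- function(code) {
  code <- as_degenerate(code, what = "IUPAC code")
  if (nchar(code) != 1L) {
    stop("iupac_code_set() expects a single character", call. = FALSE)
  }
  .iupac_sets[[code]]
}

# internal: list of per-position base sets for a validated sequence
.seq_sets <- function(seq) {
  .iupac_sets[strsplit(seq, "", fixed = TRUE)[[1]]]
}

#' Degeneracy of a degenerate sequence
#'
#' The number of distinct concrete oligonucleotides the sequence denotes:
#' the product over positions of the size of each position's IUPAC code
#' set. A fully concrete sequence has degeneracy 1.
#'
#' @param seq degenerate DNA string.
#' @return A single number (can exceed the integer range for long,
#'   highly degenerate sequences).
#' @examples
#' degeneracy("ACGT") # 1
#' degeneracy("NN")   # 16
#' degeneracy("CTKRTYAAYMRNCCVTAYATC") # 1536
#' @export
degeneracy <- function(seq) {
  seq <- as_degenerate(seq)
  prod(lengths(.seq_sets(seq)))
}

#' Expand a degenerate sequence into its concrete realisations
#'
#' Enumerates every concrete DNA sequence compatible with the degenerate
#' input. The result has exactly `degeneracy(seq)` elements. Expansion is
#' refused when the degeneracy exceeds `limit`, to prevent combinatorial
#' blow-up; raise the limit explicitly if you really want a huge set.
#'
#' @param seq degenerate DNA string.
#' @param limit maximum degeneracy that will be expanded.
#' @return Character vector of concrete sequences (lexicographic order).
#' @examples
#' expand_degenerate("RY") # AC, AT, GC, GT
#' @export
expand_degenerate <- function(seq, limit = 65536) {
  seq <- as_degenerate(seq)
  d <- degeneracy(seq)
  if (d > limit) {
    stop(
      "refusing to expand: degeneracy ", d, " exceeds limit ", limit,
      call. = FALSE
    )
  }
  sets <- .seq_sets(seq)
  out <- ""
  for (s in sets) {
    out <- as.vector(outer(out, s, paste0))
  }
  sort(out)
}

#' Reverse complement of a degenerate sequence
#'
#' Reverses the sequence and maps each IUPAC code to the code denoting
#' the complement of its base set (A<->T, C<->G, R<->Y, M<->K, S<->S,
#' W<->W, B<->V, D<->H, N<->N). An involution: `revcomp(revcomp(s)) == s`.
#'
#' @param seq degenerate DNA string.
#' @return The reverse-complemented degenerate DNA string.
#' @examples
#' revcomp("GAYTGGGG") # "CCCCARTC"
#' @export
revcomp <- function(seq) {
  seq <- as_degenerate(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Does a concrete base satisfy an IUPAC code?
#'
#' @param code single IUPAC nucleotide character.
#' @param base single concrete base (A, C, G or T).
#' @return `TRUE` iff `base` is in the code's base set.
#' @examples
#' base_matches("Y", "C") # TRUE
#' base_matches("Y", "A") # FALSE
#' @export
base_matches <- function(code, base) {
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T")) {
    stop("base must be one of A, C, G, T, got '", base, "'", call. = FALSE)
  }
  base %in% iupac_code_set(code)
}
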