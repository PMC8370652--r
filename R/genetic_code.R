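# Bacterial genetic code (NCBI translation table 11). Stored as a named
# character vector codon -> one-letter amino acid; '*' marks stop.
.genetic_code_11 <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # standard order TTT, TTC, TTA, TTG, TCT, ...
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

.stop_codons <- c("TAA", "TAG", "TGA")
.start_codons <- c("ATG", "GTG", "TTG")

#' Split a coding sequence into codons
#' @param cds_seq DNA string with length divisible by 3.
#' @return character vector of codons.
#' @keywords internal
codon_split <- function(cds_seq) {
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a multiple of 3", call. = FALSE)
  }
  substring(cds_seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    stop(what, " must be a single non-NA character string", call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop(what, " contains characters outside {A,C,G,T}: ",
         paste(bad, collapse = ", "),
         " (IUPAC ambiguity codes are rejected, not expanded)", call. = FALSE)
  }
  invisible(seq)
}

#' Translate a coding sequence (bacterial table 11)
#'
#' Translates a strand-resolved coding sequence to protein using the bacterial
#' genetic code. Alternative start codons (GTG, TTG) are rendered as 'M' at
#' position 1, matching the annotated initiator residue. The terminal stop is
#' rendered as `*`. Ambiguity codes are rejected.
#'
#' @param cds_seq DNA string over A,C,G,T; length divisible by 3.
#' @return Protein string of length `nchar(cds_seq)/3`.
#' @examples
#' translate_cds("ATGAAATGGTAA")  # "MKW*"
#' @export
translate_cds <- function(cds_seq) {
  .check_dna(cds_seq, "cds_seq")
  codons <- codon_split(cds_seq)
  aa <- .genetic_code_11[codons]
  if (length(aa) > 0L && codons[1L] %in% .start_codons) aa[1L] <- "M"
  paste(aa, collapse = "")
}

#' Map a CDS nucleotide position to (codon, offset)
#'
#' @param cds_position 1-based position within the CDS.
#' @param cds_length optional CDS length for range checking.
#' @return list with `codon_index` (1-based) and `offset` (1, 2 or 3) such that
#'   `cds_position == 3 * (codon_index - 1) + offset`.
#' @examples
#' position_to_codon(812)  # codon 271, offset 2
#' @export
position_to_codon <- function(cds_position, cds_length = NULL) {
  p <- as.integer(cds_position)
  if (is.na(p) || p < 1L) stop("cds_position must be >= 1", call. = FALSE)
  if (!is.null(cds_length) && p > cds_length) {
    stop("cds_position ", p, " is beyond CDS length ", cds_length,
         call. = FALSE)
  }
  list(codon_index = (p - 1L) %/% 3L + 1L, offset = (p - 1L) %% 3L + 1L)
}

#' Inverse of [position_to_codon()]
#' @param codon_index 1-based codon index.
#' @param offset position within codon (1..3).
#' @return 1-based CDS nucleotide position.
#' @export
codon_to_position <- function(codon_index, offset) {
  stopifnot(offset %in% 1:3, codon_index >= 1)
  3L * (as.integer(codon_index) - 1L) + as.integer(offset)
}
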