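## Small sequence helpers shared across modules.

#' Reverse-complement a nucleotide string
#'
#' Handles A/C/G/T/N plus the gap allele "-" used for indels (an insertion or
#' deletion allele reverse-complements to itself).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(out, NULL), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Translate a DNA string to amino acids
#'
#' Uses the standard genetic code. Codons containing N (or any non-ACGT
#' character) translate to "X" (unknown amino acid) rather than raising an
#' error; a trailing incomplete codon is dropped.
#'
#' @param dna a nucleotide string (length a multiple of 3, or truncated).
#' @return single-letter amino acid string ("*" is stop).
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a

## PHRED+33 string <-> integer qualities
phred_to_int <- function(s) as.integer(charToRaw(s)) - 33L
int_to_phred <- function(q) rawToChar(as.raw(q + 33L))

stop_coord <- function(...) stop("coordinate error: ", ..., call. = FALSE)
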