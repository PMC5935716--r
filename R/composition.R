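#' Nucleotide composition and strand skews
#'
#' Computes base counts, A+T content, and the strand-asymmetry skews on the
#' given (majority) strand:
#' `AT skew = (A - T) / (A + T)` and `GC skew = (G - C) / (G + C)`.
#' Ambiguity codes are excluded from all counts; a zero denominator yields
#' `NA` for the corresponding skew rather than an error.
#'
#' @param seq A single nucleotide string (or `Biostrings::DNAString`).
#' @return A one-row tibble: `a`, `c`, `g`, `t`, `length`, `at_content`
#'   (percent, 2 decimals), `at_skew`, `gc_skew`.
#' @export
#' @examples
#' composition("AAAT") # at_skew 0.5
composition <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1) stop("composition() expects a single sequence", call. = FALSE)
  counts <- vapply(
    c("A", "C", "G", "T"),
    function(b) sum(charToRaw(seq) == charToRaw(b)),
    integer(1)
  )
  a <- counts[["A"]]
  cc <- counts[["C"]]
  g <- counts[["G"]]
  t <- counts[["T"]]
  n <- a + cc + g + t
  tibble::tibble(
    a = a, c = cc, g = g, t = t,
    length = n,
    at_content = if (n > 0) round(100 * (a + t) / n, 2) else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + cc > 0) (g - cc) / (g + cc) else NA_real_
  )
}

#' Reverse complement of a nucleotide string
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement (ambiguity codes handled by Biostrings).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
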