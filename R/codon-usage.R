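.INVERT_MITO <- "SGC4" # NCBI transl_table 5, invertebrate mitochondrial

.genetic_code <- function() {
  Biostrings::getGeneticCode(.INVERT_MITO)
}

#' Codon usage and RSCU under the invertebrate mitochondrial code
#'
#' Counts codons over a set of coding sequences and computes relative
#' synonymous codon usage,
#' `RSCU(c) = count(c) * family_size / family_total`, where the family is
#' the set of synonymous codons for one amino acid. Stop codons are counted
#' but excluded from RSCU; a family with zero observations has `NA` RSCU.
#'
#' A trailing incomplete stop (1 or 2 nt beyond whole codons, i.e. the
#' truncated `T`/`TA` stops completed by polyadenylation) is trimmed before
#' counting. Any other frame violation is an error naming the sequence.
#'
#' @param cds_list Named list/vector of coding sequences (majority-strand
#'   reading; reverse-complement minority-strand genes first, e.g. with
#'   [extract_cds()]).
#' @return A tibble with columns `codon`, `aa`, `count`, `rscu`.
#' @export
#' @examples
#' codon_usage(c(g1 = "ATGTTATTGTAA"))
codon_usage <- function(cds_list) {
  code <- .genetic_code()
  counts <- stats::setNames(integer(length(code)), names(code))
  nms <- names(cds_list) %||% paste0("seq", seq_along(cds_list))
  for (i in seq_along(cds_list)) {
    s <- toupper(as.character(cds_list[[i]]))
    rem <- nchar(s) %% 3
    if (rem > 0) {
      tail_nt <- substring(s, nchar(s) - rem + 1)
      if (tail_nt %in% c("T", "TA")) {
        s <- substring(s, 1, nchar(s) - rem)
      } else {
        stop(
          "sequence ", nms[i], " is not reducible to whole codons ",
          "(trailing '", tail_nt, "' is not a truncated stop)",
          call. = FALSE
        )
      }
    }
    if (nchar(s) == 0) next
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cod <- cod[cod %in% names(counts)] # skip codons with ambiguity codes
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- tibble::tibble(
    codon = names(counts),
    aa = unname(code),
    count = as.integer(counts)
  )
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$aa),
    family_size = dplyr::n(),
    family_total = sum(.data$count),
    rscu = ifelse(
      .data$aa == "*" | .data$family_total == 0,
      NA_real_,
      .data$count * .data$family_size / .data$family_total
    )
  )
  dplyr::select(
    dplyr::ungroup(out),
    "codon", "aa", "count", "rscu"
  )
}

#' Extract coding sequences from an annotated genome
#'
#' Strand-aware extraction: minority-strand genes are read as the reverse
#' complement of their span.
#'
#' @param table An `annotation_table`.
#' @param seq The genome sequence (length must equal the table's
#'   `genome_length`).
#' @param classes Feature classes to extract (default `"PCG"`).
#' @return Named character vector of gene sequences in reading orientation.
#' @export
extract_cds <- function(table, seq, classes = "PCG") {
  seq <- toupper(as.character(seq))
  if (nchar(seq) != attr(table, "genome_length")) {
    stop("sequence length differs from annotated genome_length", call. = FALSE)
  }
  feats <- dplyr::filter(table, .data$class %in% classes)
  out <- vapply(seq_len(nrow(feats)), function(i) {
    s <- substring(seq, feats$start[i], feats$end[i])
    if (feats$strand[i] < 0) revcomp(s) else s
  }, character(1))
  stats::setNames(out, feats$gene)
}

#' Start and stop codons of annotated protein-coding genes
#'
#' The start codon is the first three nucleotides of the reading-orientation
#' sequence. The stop codon is the trailing complete codon when the length
#' is a multiple of three, otherwise the trailing `TA` or `T` (the truncated
#' stops completed by polyadenylation).
#'
#' @param table An `annotation_table`.
#' @param seq Genome sequence matching the table.
#' @return A tibble with columns `gene`, `start_codon`, `stop_codon`,
#'   `stop_truncated`.
#' @export
extract_terminal_codons <- function(table, seq) {
  cds <- extract_cds(table, seq, classes = "PCG")
  if (any(nchar(cds) < 6)) {
    stop(
      "protein-coding gene(s) shorter than 6 nt: ",
      paste(names(cds)[nchar(cds) < 6], collapse = ", "),
      call. = FALSE
    )
  }
  rem <- nchar(cds) %% 3
  stop_codon <- ifelse(
    rem == 0,
    substring(cds, nchar(cds) - 2),
    substring(cds, nchar(cds) - rem + 1)
  )
  tibble::tibble(
    gene = names(cds),
    start_codon = unname(substring(cds, 1, 3)),
    stop_codon = unname(stop_codon),
    stop_truncated = unname(rem > 0)
  )
}
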