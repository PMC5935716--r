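#' Adjacency records between consecutive annotated features
#'
#' For each consecutive feature pair on the circular genome (including the
#' wrap-around pair from the last feature back to the first) the intergenic
#' gap is `start_next - end_prev - 1`; negative values are reported as
#' overlaps, zero as abutting.
#'
#' @param table An `annotation_table` (see [read_annotation_tsv()]).
#' @return A tibble with columns `upstream`, `downstream`, `relation`
#'   (`"gap"`, `"overlap"` or `"abut"`) and `length` (bp, always >= 0).
#' @export
#' @examples
#' tj <- read_annotation_tsv(mitorearr_example("tjaponicum_annotation.tsv"))
#' adjacency_records(tj)
adjacency_records <- function(table) {
  if (nrow(table) == 0) stop("empty annotation table", call. = FALSE)
  if (is.unsorted(table$start)) {
    stop("annotation table must be sorted by start", call. = FALSE)
  }
  glen <- attr(table, "genome_length")
  if (any(table$end > glen)) {
    stop("feature(s) extend past genome_length", call. = FALSE)
  }
  n <- nrow(table)
  nxt <- c(seq_len(n)[-1], 1L)
  gap <- table$start[nxt] - table$end - 1L
  # wrap-around pair crosses the origin
  gap[n] <- (table$start[1] - 1L) + (glen - table$end[n])
  tibble::tibble(
    upstream = table$gene,
    downstream = table$gene[nxt],
    relation = dplyr::case_when(
      gap > 0 ~ "gap",
      gap < 0 ~ "overlap",
      TRUE ~ "abut"
    ),
    length = abs(gap)
  )
}

#' Per-class strand census
#'
#' Counts majority-strand (+) and minority-strand (-) genes per gene class.
#'
#' @param table An `annotation_table`.
#' @return A tibble with columns `class`, `majority`, `minority`.
#' @export
strand_census <- function(table) {
  feats <- dplyr::filter(table, .data$class != "CR")
  out <- dplyr::summarise(
    dplyr::group_by(feats, .data$class),
    majority = sum(.data$strand == 1L),
    minority = sum(.data$strand == -1L),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$class)
}

#' Genome summary statistics from an annotation table
#'
#' Aggregates adjacency records and per-class tallies: total intergenic and
#' overlapping nucleotides with their location counts, the longest spacer and
#' its flanking pair, protein-coding totals, control-region length, and tRNA
#' size range. Gaps and overlaps are derived from positions; coding totals
#' use the annotated `size` column (which defaults to the positional span).
#'
#' @param table An `annotation_table`.
#' @return A one-row tibble (`genome_summary`).
#' @export
#' @examples
#' tj <- read_annotation_tsv(mitorearr_example("tjaponicum_annotation.tsv"))
#' summarize_genome(tj)
summarize_genome <- function(table) {
  adj <- adjacency_records(table)
  gaps <- dplyr::filter(adj, .data$relation == "gap")
  ovl <- dplyr::filter(adj, .data$relation == "overlap")
  longest <- if (nrow(gaps) > 0) gaps[which.max(gaps$length), ] else NULL
  pcg <- dplyr::filter(table, .data$class == "PCG")
  trna <- dplyr::filter(table, .data$class == "tRNA")
  cr <- dplyr::filter(table, .data$class == "CR")
  glen <- attr(table, "genome_length")
  census <- strand_census(table)
  tibble::tibble(
    genome = attr(table, "genome_name"),
    genome_length = glen,
    feature_count = nrow(table),
    total_intergenic = sum(gaps$length),
    intergenic_location_count = nrow(gaps),
    longest_spacer = if (is.null(longest)) 0L else longest$length,
    longest_spacer_between = if (is.null(longest)) {
      NA_character_
    } else {
      paste(longest$upstream, longest$downstream, sep = "-")
    },
    total_overlap = sum(ovl$length),
    overlap_location_count = nrow(ovl),
    pcg_total_length = sum(pcg$size),
    pcg_fraction = round(100 * sum(pcg$size) / glen, 2),
    trna_count = nrow(trna),
    trna_min_size = if (nrow(trna) > 0) min(trna$span) else NA_integer_,
    trna_max_size = if (nrow(trna) > 0) max(trna$span) else NA_integer_,
    trna_majority = census$majority[census$class == "tRNA"] %0% 0L,
    trna_minority = census$minority[census$class == "tRNA"] %0% 0L,
    pcg_majority = census$majority[census$class == "PCG"] %0% 0L,
    pcg_minority = census$minority[census$class == "PCG"] %0% 0L,
    cr_length = if (nrow(cr) > 0) sum(cr$span) else 0L
  )
}

#' Coverage identity check
#'
#' On a circular genome tiled by its features,
#' `sum(spans) + total_intergenic - total_overlap == genome_length`.
#'
#' @param table An `annotation_table`.
#' @return Logical scalar.
#' @export
coverage_identity <- function(table) {
  adj <- adjacency_records(table)
  gaps <- sum(adj$length[adj$relation == "gap"])
  ovl <- sum(adj$length[adj$relation == "overlap"])
  sum(table$span) + gaps - ovl == attr(table, "genome_length")
}
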