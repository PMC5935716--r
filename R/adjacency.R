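#' Extremity adjacencies of a signed circular gene order
#'
#' Each gene has a tail and a head; read along the majority strand, a `+1`
#' gene spans tail-to-head and a `-1` gene head-to-tail. The adjacency
#' between two consecutive genes is the unordered pair of the extremities
#' that meet, an encoding invariant under rotation and under inversion of a
#' block for adjacencies internal to the block. `CR` is excluded by default
#' (it has no orientation).
#'
#' @param order A circular [gene_order()].
#' @param include_cr Keep `CR` as an unsigned marker (default `FALSE`).
#' @return A character vector of canonical adjacency keys, one per
#'   consecutive pair (wrap included).
#' @export
adjacency_set <- function(order, include_cr = FALSE) {
  if (!is_circular(order)) {
    stop("adjacency_set() requires a circular order", call. = FALSE)
  }
  if (!include_cr) order <- drop_cr(order)
  n <- nrow(order)
  right <- ifelse(order$orientation > 0, "h", "t") # extremity facing next gene
  left <- ifelse(order$orientation > 0, "t", "h") # extremity facing previous
  nxt <- c(seq_len(n)[-1], 1L)
  a <- paste0(order$gene, ".", right)
  b <- paste0(order$gene[nxt], ".", left[nxt])
  unname(ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|")))
}

#' Breakpoint distance between two gene orders
#'
#' The number of adjacencies of one order absent from the other; symmetric,
#' zero iff the orders are equivalent up to rotation/flip.
#'
#' @param a,b Circular [gene_order()] objects over the same gene set.
#' @param include_cr Include `CR` as an unsigned marker.
#' @return Integer distance.
#' @export
breakpoint_distance <- function(a, b, include_cr = FALSE) {
  .check_same_genes(a, b, include_cr)
  sa <- adjacency_set(a, include_cr)
  sb <- adjacency_set(b, include_cr)
  length(setdiff(sa, sb))
}

.check_same_genes <- function(a, b, include_cr = FALSE) {
  ga <- if (include_cr) a$gene else setdiff(a$gene, "CR")
  gb <- if (include_cr) b$gene else setdiff(b$gene, "CR")
  if (!setequal(ga, gb)) {
    stop(
      "gene sets differ; only in first: ",
      paste(setdiff(ga, gb), collapse = ", ") %0% "none",
      "; only in second: ",
      paste(setdiff(gb, ga), collapse = ", ") %0% "none",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Classify genes as rearranged relative to a reference order
#'
#' Default rule (`rule = "strand_or_adjacency"`): a gene is rearranged iff
#' its strand differs from the reference OR neither of its two extremity
#' adjacencies occurs in the reference. This reproduces the convention that
#' a gene which keeps its neighbours but switches strand (e.g. an in-place
#' inversion) counts as rearranged. Alternative rules: `"strict"` (both
#' adjacencies must be preserved and strand unchanged to count as
#' unrearranged) and `"position_only"` (orientation-blind: rearranged iff
#' no adjacency preserved).
#'
#' @param derived,reference Circular [gene_order()] objects over the same
#'   gene set (`CR` excluded).
#' @param rule One of `"strand_or_adjacency"`, `"strict"`, `"position_only"`.
#' @return A tibble with columns `gene`, `class`, `strand_changed`,
#'   `adjacencies_preserved` (0, 1 or 2) and `status`
#'   (`"rearranged"`/`"unrearranged"`).
#' @export
#' @examples
#' classify_rearranged(
#'   reference_orders("TrichogrammaGO"),
#'   reference_orders("PanGO")
#' )
classify_rearranged <- function(derived, reference,
                                rule = c(
                                  "strand_or_adjacency", "strict",
                                  "position_only"
                                )) {
  rule <- match.arg(rule)
  derived <- drop_cr(derived)
  reference <- drop_cr(reference)
  .check_same_genes(derived, reference)
  ref_adj <- adjacency_set(reference)
  n <- nrow(derived)
  nxt <- c(seq_len(n)[-1], 1L)
  prv <- c(n, seq_len(n)[-n])
  adj_keys <- adjacency_set(derived)
  # adjacency i sits between gene i and gene i+1
  adj_right <- adj_keys
  adj_left <- adj_keys[prv]
  preserved <- (adj_left %in% ref_adj) + (adj_right %in% ref_adj)
  ref_strand <- reference$orientation[match(derived$gene, reference$gene)]
  strand_changed <- derived$orientation != ref_strand
  status <- switch(rule,
    strand_or_adjacency = strand_changed | preserved == 0,
    strict = strand_changed | preserved < 2,
    position_only = preserved == 0
  )
  tibble::tibble(
    gene = derived$gene,
    class = gene_class(derived$gene),
    strand_changed = strand_changed,
    adjacencies_preserved = as.integer(preserved),
    status = ifelse(status, "rearranged", "unrearranged")
  )
}

#' Summary counts of rearranged genes by class
#'
#' @param classification Output of [classify_rearranged()].
#' @return A tibble with columns `class`, `rearranged`, `total`.
#' @export
rearrangement_counts <- function(classification) {
  dplyr::summarise(
    dplyr::group_by(classification, .data$class),
    rearranged = sum(.data$status == "rearranged"),
    total = dplyr::n(),
    .groups = "drop"
  )
}

#' Export a breakpoint-distance matrix in PHYLIP square format
#'
#' @param orders Named list of [gene_order()] objects over one gene set.
#' @param path Output file path.
#' @return The distance matrix, invisibly.
#' @export
write_phylip_distances <- function(orders, path) {
  nms <- names(orders)
  n <- length(orders)
  d <- matrix(0L, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- breakpoint_distance(orders[[i]], orders[[j]])
    }
  }
  lines <- c(
    sprintf("%5d", n),
    vapply(seq_len(n), function(i) {
      paste0(formatC(substr(nms[i], 1, 10), width = -10), " ", paste(d[i, ], collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(d)
}
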