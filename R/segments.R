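#' Maximal conserved segments across gene orders
#'
#' A conserved segment is a maximal run of genes that is contiguous, in the
#' same relative order and orientation, in every input order; with
#' `allow_flip` (default) an order also carries a segment when it contains
#' the whole segment inverted. Maximality: extending a reported segment by
#' one gene breaks conservation in at least one order.
#'
#' @param orders List of >= 2 circular [gene_order()] objects over a common
#'   gene set.
#' @param min_len Minimum segment length in genes (default 2).
#' @param allow_flip Count whole-segment inversions as carrying.
#' @param include_cr Include `CR` as an unsigned marker.
#' @return A tibble sorted by decreasing length: `segment` (signed-token
#'   string read in the first order's frame), `length`, `genes` (list column
#'   of per-gene tibbles).
#' @export
#' @examples
#' shared_segments(reference_orders()[c("PanGO", "TrichogrammaGO")])
shared_segments <- function(orders, min_len = 2, allow_flip = TRUE,
                            include_cr = FALSE) {
  stopifnot(length(orders) >= 2)
  if (!include_cr) orders <- lapply(orders, drop_cr)
  ref <- orders[[1]]
  for (o in orders[-1]) .check_same_genes(ref, o, include_cr = TRUE)
  pres <- rep(TRUE, nrow(ref))
  for (o in orders[-1]) {
    pres <- pres & .pairs_preserved(ref, o, allow_flip)
  }
  .segments_from_pairs(ref, pres, min_len)
}

# For each consecutive reference pair (i, i+1; wrap at n): is the signed
# adjacency present in `other` (forward, or reversed-negated when allow_flip)?
.pairs_preserved <- function(ref, other, allow_flip = TRUE) {
  n <- nrow(ref)
  nxt <- c(seq_len(n)[-1], 1L)
  m <- nrow(other)
  onxt <- c(seq_len(m)[-1], 1L)
  pos <- match(ref$gene, other$gene)
  sign_in_other <- other$orientation[pos]
  next_gene <- other$gene[onxt][pos]
  next_sign <- other$orientation[onxt][pos]
  oprv <- c(m, seq_len(m)[-m])
  prev_gene <- other$gene[oprv][pos]
  prev_sign <- other$orientation[oprv][pos]

  g1 <- seq_len(n)
  g2 <- nxt
  fwd <- sign_in_other[g1] == ref$orientation[g1] &
    next_gene[g1] == ref$gene[g2] &
    next_sign[g1] == ref$orientation[g2]
  if (!allow_flip) {
    return(fwd)
  }
  rev <- sign_in_other[g1] == -ref$orientation[g1] &
    prev_gene[g1] == ref$gene[g2] &
    prev_sign[g1] == -ref$orientation[g2]
  fwd | rev
}

.segments_from_pairs <- function(ref, pres, min_len) {
  n <- nrow(ref)
  empty <- tibble::tibble(
    segment = character(), length = integer(), genes = list()
  )
  seg_tbl <- function(idx) {
    g <- ref[idx, c("gene", "orientation")]
    tibble::tibble(
      segment = paste0(
        ifelse(g$orientation < 0, "-", ""), g$gene,
        collapse = " "
      ),
      length = length(idx),
      genes = list(tibble::as_tibble(g))
    )
  }
  if (all(pres)) {
    return(seg_tbl(seq_len(n)))
  }
  # linearize the circle at a broken pair, then take maximal TRUE runs
  brk <- which(!pres)[1]
  ord <- ((brk:(brk + n - 1) - 1L) %% n) + 1L # pair indices, broken pair first
  runs <- rle(pres[ord])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values)) {
    pair_idx <- ord[starts[k]:ends[k]]
    # pairs i..j cover genes i..j+1
    gene_idx <- ((pair_idx[1] + seq_len(length(pair_idx) + 1L) - 2L) %% n) + 1L
    if (length(gene_idx) >= min_len) {
      out[[length(out) + 1]] <- seg_tbl(gene_idx)
    }
  }
  if (length(out) == 0) {
    return(empty)
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, dplyr::desc(.data$length))
}

#' Does an order carry a signed segment?
#'
#' @param order A circular [gene_order()].
#' @param segment A tibble with columns `gene`, `orientation` (or a
#'   [gene_order()] / signed-token string).
#' @param allow_flip Accept the whole-segment inversion.
#' @return Logical.
#' @export
carries_segment <- function(order, segment, allow_flip = TRUE) {
  seg <- .as_segment(segment)
  k <- nrow(seg)
  if (k == 0) {
    return(TRUE)
  }
  o <- drop_cr(order)
  n <- nrow(o)
  if (k > n) {
    return(FALSE)
  }
  probe <- function(genes, signs) {
    start <- match(genes[1], o$gene)
    if (is.na(start) || o$orientation[start] != signs[1]) {
      return(FALSE)
    }
    idx <- ((start + seq_len(k) - 2L) %% n) + 1L
    all(o$gene[idx] == genes) && all(o$orientation[idx] == signs)
  }
  if (probe(seg$gene, seg$orientation)) {
    return(TRUE)
  }
  allow_flip && probe(rev(seg$gene), -rev(seg$orientation))
}

.as_segment <- function(segment) {
  if (is.character(segment) && length(segment) == 1) {
    segment <- parse_gene_order(segment)
  }
  tibble::tibble(
    gene = segment$gene,
    orientation = as.integer(segment$orientation)
  )
}
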