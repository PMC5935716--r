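#' Signed circular gene orders
#'
#' A `gene_order` is an ordered set of oriented genes on a (by default)
#' circular molecule. Orientation is relative to the majority strand of the
#' genome: `+1` for majority-strand genes, `-1` for minority-strand genes.
#' The control-region marker `CR` carries no real orientation and is stored
#' as `+1`.
#'
#' @param genes Character vector of gene tokens (canonical or aliases).
#' @param orientation Integer vector of `+1`/`-1`, recycled if length 1.
#' @param name Free-text name of the arrangement.
#' @param circular Logical; circular molecule (default `TRUE`).
#' @param metadata Optional named list (e.g. transcription confidence).
#' @return An object of class `gene_order`: a tibble with columns `gene` and
#'   `orientation` plus attributes `name`, `circular`, `metadata`.
#' @export
#' @examples
#' gene_order(c("trnS2", "nad1", "trnL1", "rrnL"), c(1, -1, -1, -1))
gene_order <- function(genes, orientation = 1L, name = "",
                       circular = TRUE, metadata = list()) {
  genes <- canonical_gene(genes)
  orientation <- as.integer(rep(orientation, length.out = length(genes)))
  if (!all(orientation %in% c(-1L, 1L))) {
    stop("orientation must be +1 or -1", call. = FALSE)
  }
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop(
      "duplicated gene(s) in order: ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  orientation[genes == "CR"] <- 1L
  out <- tibble::tibble(gene = genes, orientation = orientation)
  structure(
    out,
    name = name,
    circular = isTRUE(circular),
    metadata = metadata,
    class = c("gene_order", class(out))
  )
}

#' @export
print.gene_order <- function(x, ...) {
  nm <- attr(x, "name")
  cat(
    "<gene_order",
    if (nzchar(nm)) paste0(" '", nm, "'"),
    ": ", nrow(x), " genes, ",
    if (attr(x, "circular")) "circular" else "linear",
    ">\n",
    sep = ""
  )
  cat(format_gene_order(x, names = FALSE), "\n")
  invisible(x)
}

order_name <- function(x) attr(x, "name")
is_circular <- function(x) isTRUE(attr(x, "circular"))

#' Parse a signed gene-order string
#'
#' Tokens are whitespace-separated gene names, with a leading `-` marking
#' genes on the minority strand, e.g. `"trnS2 -nad1 -trnL1 -rrnL"`.
#'
#' @param text A single string of signed tokens.
#' @param name Name for the resulting order.
#' @param circular Logical, default `TRUE`.
#' @return A [gene_order()].
#' @export
#' @examples
#' parse_gene_order("trnS2 -nad1 -trnL1 -rrnL")
parse_gene_order <- function(text, name = "", circular = TRUE) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    stop("empty gene-order string", call. = FALSE)
  }
  neg <- startsWith(tokens, "-")
  raw <- ifelse(neg, substring(tokens, 2), tokens)
  gene_order(raw, ifelse(neg, -1L, 1L), name = name, circular = circular)
}

#' Serialize a gene order to signed-token text
#'
#' @param order A [gene_order()].
#' @param names If `TRUE`, prefix with `"name: "` (the gene-order file
#'   record format).
#' @return A single string; parsing it back is the identity.
#' @export
format_gene_order <- function(order, names = FALSE) {
  toks <- paste0(ifelse(order$orientation < 0, "-", ""), order$gene)
  body <- paste(toks, collapse = " ")
  if (names) paste0(order_name(order), ": ", body) else body
}

#' Read and write gene-order text files
#'
#' One genome per record, `"name: tok tok -tok ..."`; `#` starts a comment.
#'
#' @param path File path.
#' @return `read_gene_orders()`: a named list of [gene_order()] objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("malformed gene-order record: ", ln, call. = FALSE)
    }
    nm <- trimws(parts[1])
    out[[nm]] <- parse_gene_order(parts[2], name = nm)
  }
  out
}

#' @rdname read_gene_orders
#' @param orders A named list of [gene_order()] objects (or a single one).
#' @export
write_gene_orders <- function(orders, path) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  lines <- vapply(orders, format_gene_order, character(1), names = TRUE)
  writeLines(lines, path)
  invisible(path)
}

.rebuild_order <- function(template, genes, orientation) {
  gene_order(
    genes, orientation,
    name = attr(template, "name"),
    circular = attr(template, "circular"),
    metadata = attr(template, "metadata")
  )
}

rotate_order <- function(order, k) {
  n <- nrow(order)
  k <- ((k - 1) %% n) + 1
  idx <- c(seq(k, n), if (k > 1) seq(1, k - 1))
  .rebuild_order(order, order$gene[idx], order$orientation[idx])
}

flip_order <- function(order) {
  idx <- rev(seq_len(nrow(order)))
  .rebuild_order(order, order$gene[idx], -order$orientation[idx])
}

#' Linearize a circular gene order at an anchor gene
#'
#' Rotates the order so `anchor` comes first. With `forward = FALSE` the
#' whole molecule is flipped (sequence reversed, orientations negated)
#' before rotation, so the anchor reads `+1`.
#'
#' @param order A circular [gene_order()].
#' @param anchor Gene token to place first.
#' @param forward If `FALSE`, flip the molecule so the anchor reads `+1`.
#' @return A [gene_order()] starting at `anchor`.
#' @export
linearize <- function(order, anchor, forward = TRUE) {
  anchor <- canonical_gene(anchor)
  pos <- match(anchor, order$gene)
  if (is.na(pos)) {
    stop("anchor gene not present in order: ", anchor, call. = FALSE)
  }
  if (!forward) {
    order <- flip_order(order)
    pos <- match(anchor, order$gene)
  }
  rotate_order(order, pos)
}

#' Test equivalence of circular gene orders
#'
#' Two circular orders are equivalent when some rotation (and, when
#' `allow_flip`, a whole-molecule flip) of one matches the other
#' gene-for-gene with orientations.
#'
#' @param a,b [gene_order()] objects over the same gene set.
#' @param allow_flip Also try the flipped molecule (default `TRUE`).
#' @return Logical.
#' @export
orders_equivalent <- function(a, b, allow_flip = TRUE) {
  if (!setequal(a$gene, b$gene)) {
    stop(
      "orders have different gene sets; only in a: ",
      paste(setdiff(a$gene, b$gene), collapse = ", "),
      "; only in b: ", paste(setdiff(b$gene, a$gene), collapse = ", "),
      call. = FALSE
    )
  }
  same <- function(x, y) {
    all(x$gene == y$gene) && all(x$orientation == y$orientation)
  }
  cand <- list(b)
  if (allow_flip) cand <- c(cand, list(flip_order(b)))
  for (bb in cand) {
    k <- match(a$gene[1], bb$gene)
    if (same(a, rotate_order(bb, k))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Derive a gene order from an annotation table
#'
#' Features are sorted by start coordinate; the strand column maps onto
#' orientation. The control region is appended only when `include_cr`.
#'
#' @param table An annotation table (see [read_annotation_tsv()]).
#' @param include_cr Keep the `CR` marker (default `TRUE`).
#' @param name Name of the resulting order; defaults to the genome name.
#' @return A circular [gene_order()].
#' @export
order_from_annotation <- function(table, include_cr = TRUE, name = NULL) {
  feats <- dplyr::arrange(table, .data$start)
  if (!include_cr) feats <- dplyr::filter(feats, .data$gene != "CR")
  gene_order(
    feats$gene, feats$strand,
    name = name %||% attr(table, "genome_name") %||% "",
    circular = TRUE
  )
}

#' Drop the control-region marker from an order
#'
#' Permutation-based computations act on the 37 oriented genes; `CR` has no
#' orientation and is excluded by default there.
#'
#' @param order A [gene_order()].
#' @return The order without `CR`.
#' @export
drop_cr <- function(order) {
  if (!"CR" %in% order$gene) {
    return(order)
  }
  keep <- order$gene != "CR"
  .rebuild_order(order, order$gene[keep], order$orientation[keep])
}
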