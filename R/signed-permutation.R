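#' Encode a derived gene order as a signed permutation of a reference
#'
#' The reference order is linearized at `anchor` and its genes labelled
#' `1..n` (all `+`); the derived order is linearized at the same anchor,
#' flipped if necessary so the anchor keeps its reference orientation, and
#' read in those labels. The reference thus maps to the identity; a derived
#' gene carries a negative label when its strand differs from the reference.
#' `CR` is excluded (it has no orientation).
#'
#' @param derived,reference Circular [gene_order()] objects over the same
#'   gene set.
#' @param anchor Gene used for linearization (default `"cob"`).
#' @return A `signed_permutation`: list with `perm` (signed integer vector),
#'   `genes` (label-to-gene lookup), `ref_orientation`, `anchor`.
#' @export
#' @examples
#' to_signed_permutation(
#'   reference_orders("TrichogrammaGO"),
#'   reference_orders("ChalcidoidGO")
#' )
to_signed_permutation <- function(derived, reference, anchor = "cob") {
  derived <- drop_cr(derived)
  reference <- drop_cr(reference)
  .check_same_genes(derived, reference)
  anchor <- canonical_gene(anchor)
  ref_lin <- linearize(reference, anchor, forward = TRUE)
  ref_sign <- stats::setNames(ref_lin$orientation, ref_lin$gene)
  der_anchor_sign <- derived$orientation[match(anchor, derived$gene)]
  der_lin <- if (der_anchor_sign == ref_sign[[anchor]]) {
    linearize(derived, anchor, forward = TRUE)
  } else {
    linearize(derived, anchor, forward = FALSE)
  }
  label <- stats::setNames(seq_len(nrow(ref_lin)), ref_lin$gene)
  perm <- unname(label[der_lin$gene]) *
    der_lin$orientation * unname(ref_sign[der_lin$gene])
  structure(
    list(
      perm = as.integer(perm),
      genes = ref_lin$gene,
      ref_orientation = unname(ref_lin$orientation),
      anchor = anchor
    ),
    class = "signed_permutation"
  )
}

#' @export
print.signed_permutation <- function(x, ...) {
  cat(
    "<signed_permutation n=", length(x$perm), ", anchor=", x$anchor, ">\n",
    paste(x$perm, collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Common intervals of a signed permutation against the identity
#'
#' A common interval is a set of consecutive values `a..b` occupying
#' consecutive positions in the permutation (in any order and orientation).
#'
#' @param perm A signed integer permutation vector (or `signed_permutation`).
#' @return A tibble with columns `a`, `b` (value range, `b > a` or `a == b`
#'   excluded: only intervals of length >= 2 plus, implicitly, singletons).
#' @export
common_intervals <- function(perm) {
  ci <- .ci_matrix(.as_perm(perm))
  tibble::tibble(a = ci[, 1], b = ci[, 2])
}

# two-column matrix of common intervals (length >= 2), plain integer math
.ci_matrix <- function(p) {
  n <- length(p)
  pos <- integer(n)
  pos[abs(p)] <- seq_len(n)
  res <- vector("list", n)
  for (a in seq_len(max(n - 1, 0))) {
    if (a == n) break
    rng <- (a + 1):n
    mn <- cummin(pos[a:n])[-1]
    mx <- cummax(pos[a:n])[-1]
    hit <- rng[(mx - mn) == (rng - a)]
    if (length(hit) > 0) res[[a]] <- cbind(a, hit)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("a", "b")
  out
}

.as_perm <- function(perm) {
  if (inherits(perm, "signed_permutation")) perm <- perm$perm
  p <- as.integer(perm)
  if (!identical(sort(abs(p)), seq_along(p))) {
    stop("not a permutation of 1..n", call. = FALSE)
  }
  p
}

#' Strong common intervals
#'
#' A common interval is strong when it overlaps (properly crosses) no other
#' common interval. Singletons and the full interval are always strong.
#'
#' @inheritParams common_intervals
#' @return A tibble with columns `a`, `b`, including singletons and the full
#'   interval.
#' @export
strong_intervals <- function(perm) {
  si <- .si_matrix(.as_perm(perm))
  tibble::tibble(a = si[, 1], b = si[, 2])
}

.si_matrix <- function(p) {
  n <- length(p)
  ci <- .ci_matrix(p)
  cand <- rbind(ci, cbind(seq_len(n), seq_len(n)), c(1L, n))
  cand <- unique(cand)
  ca <- ci[, 1]
  cb <- ci[, 2]
  crosses <- vapply(seq_len(nrow(cand)), function(i) {
    a <- cand[i, 1]
    b <- cand[i, 2]
    any((ca < a & cb >= a & cb < b) | (ca > a & ca <= b & cb > b))
  }, logical(1))
  out <- cand[!crosses, , drop = FALSE]
  out[order(out[, 1], -out[, 2]), , drop = FALSE]
}

#' Strong interval tree of a signed permutation
#'
#' Organizes the strong common intervals (versus the identity) by inclusion.
#' Each internal node is labelled by the order of its children blocks in the
#' permutation: `linear_inc` (ascending value ranges), `linear_dec`
#' (descending), or `prime`.
#'
#' @inheritParams common_intervals
#' @return A `strong_interval_tree`: nested list of nodes, each with
#'   `a`, `b` (value range), `type`, and `children`.
#' @export
#' @examples
#' strong_interval_tree(c(1L, -3L, -2L))
strong_interval_tree <- function(perm) {
  p <- .as_perm(perm)
  n <- length(p)
  pos <- integer(n)
  pos[abs(p)] <- seq_len(n)
  si <- .si_matrix(p)
  # laterally nested: stack construction over (a asc, b desc)
  make_node <- function(a, b) {
    list(a = a, b = b, children = list(), type = "leaf")
  }
  root <- NULL
  stack <- list()
  for (i in seq_len(nrow(si))) {
    node <- make_node(si[i, 1], si[i, 2])
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      if (node$a >= top$a && node$b <= top$b &&
        !(node$a == top$a && node$b == top$b)) {
        break
      }
      # top is complete: attach to its parent
      stack[[length(stack)]] <- NULL
      top <- .label_node(top, pos)
      if (length(stack) == 0) {
        root <- top
      } else {
        parent <- stack[[length(stack)]]
        parent$children[[length(parent$children) + 1]] <- top
        stack[[length(stack)]] <- parent
      }
    }
    stack[[length(stack) + 1]] <- node
  }
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    top <- .label_node(top, pos)
    if (length(stack) == 0) {
      root <- top
    } else {
      parent <- stack[[length(stack)]]
      parent$children[[length(parent$children) + 1]] <- top
      stack[[length(stack)]] <- parent
    }
  }
  structure(list(root = root, perm = p), class = "strong_interval_tree")
}

.label_node <- function(node, pos) {
  k <- length(node$children)
  if (k == 0) {
    node$type <- "leaf"
    return(node)
  }
  # order children by their position in the permutation
  child_pos <- vapply(node$children, function(ch) min(pos[ch$a:ch$b]), numeric(1))
  node$children <- node$children[order(child_pos)]
  lo <- vapply(node$children, function(ch) ch$a, integer(1))
  node$type <- if (all(diff(lo) > 0)) {
    "linear_inc"
  } else if (all(diff(lo) < 0)) {
    "linear_dec"
  } else {
    "prime"
  }
  node
}

#' @export
print.strong_interval_tree <- function(x, ...) {
  rec <- function(node, depth) {
    cat(
      strrep("  ", depth), "[", node$a,
      if (node$b > node$a) paste0("..", node$b), "] ", node$type, "\n",
      sep = ""
    )
    for (ch in node$children) rec(ch, depth + 1)
  }
  rec(x$root, 0)
  invisible(x)
}

#' Flatten a strong interval tree to its node set
#'
#' @param tree A `strong_interval_tree`.
#' @return A tibble with columns `a`, `b`, `type`.
#' @export
tree_nodes <- function(tree) {
  a <- integer(0)
  b <- integer(0)
  ty <- character(0)
  rec <- function(node) {
    a[[length(a) + 1]] <<- node$a
    b[[length(b) + 1]] <<- node$b
    ty[[length(ty) + 1]] <<- node$type
    for (ch in node$children) rec(ch)
  }
  rec(tree$root)
  ord <- order(a, -b)
  tibble::tibble(a = a[ord], b = b[ord], type = ty[ord])
}
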