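#' Assemble a presumed ancestral gene order from conserved segments
#'
#' A rule-based formalization of manual ancestral-gene-order reasoning:
#'
#' 1. candidate segments are all maximal segments shared between an ingroup
#'    order and an outgroup (provenance `shared-with-outgroup`) and all
#'    maximal segments shared by at least `min_ingroup_support` ingroup
#'    orders (provenance `shared-within-ingroup`);
#' 2. candidates are placed greedily by decreasing length, with
#'    shared-with-outgroup outranking ingroup-only at equal length and
#'    remaining ties broken by the first-listed carrier; a candidate
#'    overlapping already-placed genes is skipped;
#' 3. genes left uncovered default to the first outgroup's arrangement
#'    (provenance `defaulted-to-outgroup`);
#' 4. segments are stitched in the order their gene content occupies in the
#'    first outgroup, oriented to match the outgroup flanks of the carrier.
#'
#' Two refinements mirror how such arguments are actually made: ingroup
#' orders with equivalent arrangements collapse into one arrangement class
#' (identical sister taxa are a single character state, so they cannot vouch
#' for themselves), and a qualifying ingroup-only segment may be extended
#' within a single carrier over neighbouring strand-changed genes whose
#' adjacencies are plesiomorphic in the outgroup — a larger in-place
#' inversion whose interior adjacencies match the ground pattern is taken as
#' evidence for the larger ancestral block.
#'
#' @param ingroup Named list of circular [gene_order()] objects.
#' @param outgroups Named list of outgroup ground-pattern orders (>= 1).
#' @param min_ingroup_support Minimum number of distinct ingroup arrangement
#'   classes that must carry an ingroup-only candidate (default 2).
#' @return An `ancestral_call`: list with `order` (the assembled circular
#'   [gene_order()]) and `segments` (tibble with provenance and supporting
#'   taxa per placed segment).
#' @export
#' @examples
#' reg <- reference_orders()
#' call <- infer_ancestral(
#'   reg[c(
#'     "TrichogrammaGO", "Megaphragma", "Philotrypesis", "Ceratosolen",
#'     "Nasonia_vitripennis", "Nasonia_giraulti"
#'   )],
#'   reg[c("ant1GO", "PanGO")]
#' )
#' orders_equivalent(call$order, reg$ChalcidoidGO)
infer_ancestral <- function(ingroup, outgroups, min_ingroup_support = 2) {
  stopifnot(length(ingroup) >= 1, length(outgroups) >= 1)
  if (is.null(names(ingroup))) names(ingroup) <- paste0("ingroup", seq_along(ingroup))
  if (is.null(names(outgroups))) names(outgroups) <- paste0("outgroup", seq_along(outgroups))
  og1 <- outgroups[[1]]
  cr_left_neighbour <- if ("CR" %in% og1$gene) {
    n1 <- nrow(og1)
    og1$gene[((match("CR", og1$gene) - 2L) %% n1) + 1L]
  }
  ingroup <- lapply(ingroup, drop_cr)
  outgroups <- lapply(outgroups, drop_cr)
  ref_out <- outgroups[[1]]
  for (o in c(ingroup, outgroups)) .check_same_genes(ref_out, o)
  ingroup <- .collapse_arrangement_classes(ingroup)

  cands <- .candidate_segments(ingroup, outgroups, min_ingroup_support)
  # placement priority: length desc, outgroup-shared first, carrier order
  cands <- cands[order(
    -cands$length,
    cands$provenance != "shared-with-outgroup",
    cands$first_carrier
  ), ]

  covered <- character(0)
  placed <- list()
  for (i in seq_len(nrow(cands))) {
    genes_i <- cands$genes[[i]]$gene
    if (any(genes_i %in% covered)) next
    placed[[length(placed) + 1]] <- cands[i, ]
    covered <- c(covered, genes_i)
  }
  # fill uncovered genes from the first outgroup's arrangement
  left <- setdiff(ref_out$gene, covered)
  if (length(left) > 0) {
    idx <- which(ref_out$gene %in% left)
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (run in runs) {
      placed[[length(placed) + 1]] <- tibble::tibble(
        segment = paste0(
          ifelse(ref_out$orientation[run] < 0, "-", ""),
          ref_out$gene[run],
          collapse = " "
        ),
        length = length(run),
        genes = list(tibble::tibble(
          gene = ref_out$gene[run],
          orientation = ref_out$orientation[run]
        )),
        provenance = "defaulted-to-outgroup",
        support = list(names(outgroups)[1]),
        first_carrier = names(outgroups)[1]
      )
    }
  }
  segs <- dplyr::bind_rows(placed)
  segs <- .orient_and_order_segments(segs, ref_out, ingroup)
  assembled <- dplyr::bind_rows(segs$genes)
  # CR (excluded from segment math) is reattached after the gene it follows
  # in the first outgroup, so wrap-around segments cannot displace it
  if (!is.null(cr_left_neighbour)) {
    at <- match(cr_left_neighbour, assembled$gene)
    assembled <- dplyr::bind_rows(
      assembled[seq_len(at), ],
      tibble::tibble(gene = "CR", orientation = 1L),
      if (at < nrow(assembled)) assembled[(at + 1):nrow(assembled), ]
    )
  }
  order_out <- gene_order(
    assembled$gene, assembled$orientation,
    name = "ancestral_call", circular = TRUE
  )
  structure(
    list(order = order_out, segments = segs),
    class = "ancestral_call"
  )
}

# pool of maximal pairwise candidates with provenance and support counts
.candidate_segments <- function(ingroup, outgroups, min_ingroup_support) {
  pool <- list()
  add <- function(seg_row, carrier_pair) {
    key <- seg_row$segment
    flip_key <- .flip_segment_key(seg_row$genes[[1]])
    k <- if (key %in% names(pool)) key else if (flip_key %in% names(pool)) flip_key else key
    if (is.null(pool[[k]])) {
      seg_row$support <- list(carrier_pair)
      pool[[k]] <<- seg_row
    } else {
      pool[[k]]$support[[1]] <<- union(pool[[k]]$support[[1]], carrier_pair)
    }
  }
  for (i in names(ingroup)) {
    for (o in names(outgroups)) {
      # outgroup first: candidate readings are in the outgroup frame
      segs <- shared_segments(list(outgroups[[o]], ingroup[[i]]))
      for (r in seq_len(nrow(segs))) {
        row <- segs[r, ]
        row$provenance <- "shared-with-outgroup"
        row$first_carrier <- i
        add(row, c(i, o))
      }
    }
  }
  nms <- names(ingroup)
  if (length(nms) >= 2) {
    for (a in seq_along(nms)) {
      for (b in seq_along(nms)) {
        if (b <= a) next
        segs <- shared_segments(list(ingroup[[nms[a]]], ingroup[[nms[b]]]))
        for (r in seq_len(nrow(segs))) {
          row <- segs[r, ]
          row$provenance <- "shared-within-ingroup"
          row$first_carrier <- nms[a]
          add(row, c(nms[a], nms[b]))
        }
      }
    }
  }
  if (length(pool) == 0) {
    return(tibble::tibble(
      segment = character(), length = integer(), genes = list(),
      provenance = character(), support = list(), first_carrier = character()
    ))
  }
  out <- dplyr::bind_rows(pool)
  # outgroup-backed candidates always qualify; ingroup-only ones need support
  ingroup_support <- vapply(
    out$support,
    function(s) sum(s %in% names(ingroup)), integer(1)
  )
  keep <- out$provenance == "shared-with-outgroup" |
    ingroup_support >= min_ingroup_support
  out <- out[keep, ]
  .extend_candidates(out, ingroup, outgroups)
}

# collapse equivalent arrangements into one carrier class (first name wins)
.collapse_arrangement_classes <- function(ingroup) {
  reps <- list()
  for (nm in names(ingroup)) {
    dup <- FALSE
    for (rnm in names(reps)) {
      if (orders_equivalent(ingroup[[nm]], reps[[rnm]], allow_flip = TRUE)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) reps[[nm]] <- ingroup[[nm]]
  }
  reps
}

# canonical keys for the signed adjacencies of an order (a pair and its
# reverse complement share a key)
.signed_pairs <- function(order) {
  n <- nrow(order)
  nxt <- c(seq_len(n)[-1], 1L)
  a <- paste0(ifelse(order$orientation > 0, "", "-"), order$gene)
  b <- a[nxt]
  ra <- paste0(ifelse(order$orientation[nxt] > 0, "-", ""), order$gene[nxt])
  rb <- paste0(ifelse(order$orientation > 0, "-", ""), order$gene)
  fwd <- paste(a, b)
  rev <- paste(ra, rb)
  unique(ifelse(fwd < rev, paste(fwd, rev), paste(rev, fwd)))
}

# grow qualifying ingroup-only candidates within each carrier across
# adjacencies that are plesiomorphic in an outgroup
.extend_candidates <- function(cands, ingroup, outgroups) {
  if (nrow(cands) == 0) {
    return(cands)
  }
  og_pairs <- unique(unlist(lapply(outgroups, .signed_pairs)))
  pair_key <- function(g1, s1, g2, s2) {
    fwd <- paste(
      paste0(ifelse(s1 > 0, "", "-"), g1),
      paste0(ifelse(s2 > 0, "", "-"), g2)
    )
    rev <- paste(
      paste0(ifelse(s2 > 0, "-", ""), g2),
      paste0(ifelse(s1 > 0, "-", ""), g1)
    )
    ifelse(fwd < rev, paste(fwd, rev), paste(rev, fwd))
  }
  ref_out <- outgroups[[1]]
  out_strand <- stats::setNames(ref_out$orientation, ref_out$gene)
  extra <- list()
  base <- cands[cands$provenance == "shared-within-ingroup", ]
  for (i in seq_len(nrow(base))) {
    g <- base$genes[[i]]
    for (nm in names(ingroup)) {
      o <- ingroup[[nm]]
      n <- nrow(o)
      occ <- .locate_occurrence(o, g)
      if (is.null(occ)) next
      idx <- occ # positions of the segment in o, in o's reading order
      lo <- idx[1]
      hi <- idx[length(idx)]
      grow <- 0L
      # a gene joins the block only if it lies on the opposite strand from
      # the outgroup and joins across an adjacency the outgroup also has
      repeat { # grow left
        prev <- ((lo - 2L) %% n) + 1L
        if (length(idx) + grow >= n - 1L) break
        k <- pair_key(
          o$gene[prev], o$orientation[prev],
          o$gene[lo], o$orientation[lo]
        )
        if (!(k %in% og_pairs) ||
          o$orientation[prev] != -out_strand[[o$gene[prev]]]) {
          break
        }
        lo <- prev
        grow <- grow + 1L
      }
      repeat { # grow right
        nxt <- (hi %% n) + 1L
        if (length(idx) + grow >= n - 1L) break
        k <- pair_key(
          o$gene[hi], o$orientation[hi],
          o$gene[nxt], o$orientation[nxt]
        )
        if (!(k %in% og_pairs) ||
          o$orientation[nxt] != -out_strand[[o$gene[nxt]]]) {
          break
        }
        hi <- nxt
        grow <- grow + 1L
      }
      if (grow == 0L) next
      span <- if (lo <= hi) lo:hi else c(lo:n, 1:hi)
      gg <- tibble::tibble(gene = o$gene[span], orientation = o$orientation[span])
      supp <- names(ingroup)[vapply(
        ingroup,
        function(x) carries_segment(x, gg), logical(1)
      )]
      extra[[length(extra) + 1]] <- tibble::tibble(
        segment = paste0(ifelse(gg$orientation < 0, "-", ""), gg$gene, collapse = " "),
        length = nrow(gg),
        genes = list(gg),
        provenance = "shared-within-ingroup",
        support = list(supp),
        first_carrier = nm
      )
    }
  }
  if (length(extra) == 0) {
    return(cands)
  }
  out <- dplyr::bind_rows(cands, dplyr::bind_rows(extra))
  dplyr::distinct(out, .data$segment, .keep_all = TRUE)
}

# positions of a signed segment occurrence in an order (forward reading),
# or of its flip (returned in the order's reading direction); NULL if absent
.locate_occurrence <- function(o, g) {
  n <- nrow(o)
  k <- nrow(g)
  start <- match(g$gene[1], o$gene)
  idx <- ((start + seq_len(k) - 2L) %% n) + 1L
  if (!is.na(start) && all(o$gene[idx] == g$gene) &&
    all(o$orientation[idx] == g$orientation)) {
    return(idx)
  }
  start2 <- match(g$gene[k], o$gene)
  if (is.na(start2)) {
    return(NULL)
  }
  idx2 <- ((start2 + seq_len(k) - 2L) %% n) + 1L
  if (all(o$gene[idx2] == rev(g$gene)) &&
    all(o$orientation[idx2] == -rev(g$orientation))) {
    return(idx2)
  }
  NULL
}

.flip_segment_key <- function(genes) {
  paste0(
    ifelse(rev(genes$orientation) > 0, "-", ""), rev(genes$gene),
    collapse = " "
  )
}

# order segments along the first outgroup; ingroup-only segments are
# oriented so the carrier's flanking genes match the outgroup neighbours of
# the segment's gene content (an inverted-in-place block keeps its inverted
# reading; a block that matches the frame stays as read)
.orient_and_order_segments <- function(segs, ref_out, ingroup) {
  n <- nrow(ref_out)
  pos <- stats::setNames(seq_len(n), ref_out$gene)
  minpos <- vapply(segs$genes, function(g) min(pos[g$gene]), numeric(1))
  segs <- segs[order(minpos), ]
  for (i in seq_len(nrow(segs))) {
    if (segs$provenance[i] != "shared-within-ingroup") next
    g <- segs$genes[[i]]
    idx <- sort(pos[g$gene])
    contiguous <- (idx[length(idx)] - idx[1] + 1L) == nrow(g)
    if (!contiguous) next
    og_before <- ref_out$gene[((idx[1] - 2L) %% n) + 1L]
    og_after <- ref_out$gene[(idx[length(idx)] %% n) + 1L]
    carrier <- ingroup[[segs$first_carrier[i]]]
    fl <- .segment_flanks(carrier, g)
    if (is.null(fl)) next
    score_keep <- (fl$before == og_before) + (fl$after == og_after)
    score_flip <- (fl$after == og_before) + (fl$before == og_after)
    if (score_flip > score_keep) {
      segs$segment[i] <- .flip_segment_key(g)
      segs$genes[[i]] <- tibble::tibble(
        gene = rev(g$gene), orientation = -rev(g$orientation)
      )
    }
  }
  segs
}

# tokens adjacent to a segment occurrence in `carrier`, expressed relative to
# the stored reading direction (before = adjacent to the segment's first
# gene, after = adjacent to its last)
.segment_flanks <- function(carrier, g) {
  o <- drop_cr(carrier)
  n <- nrow(o)
  k <- nrow(g)
  start <- match(g$gene[1], o$gene)
  if (is.na(start)) {
    return(NULL)
  }
  idx <- ((start + seq_len(k) - 2L) %% n) + 1L
  if (all(o$gene[idx] == g$gene) && all(o$orientation[idx] == g$orientation)) {
    return(list(
      before = o$gene[((start - 2L) %% n) + 1L],
      after = o$gene[(idx[k] %% n) + 1L]
    ))
  }
  # flipped occurrence: carrier holds rev(-g); locate by the last gene
  start2 <- match(g$gene[k], o$gene)
  if (is.na(start2)) {
    return(NULL)
  }
  idx2 <- ((start2 + seq_len(k) - 2L) %% n) + 1L
  if (all(o$gene[idx2] == rev(g$gene)) &&
    all(o$orientation[idx2] == -rev(g$orientation))) {
    return(list(
      before = o$gene[(idx2[k] %% n) + 1L],
      after = o$gene[((start2 - 2L) %% n) + 1L]
    ))
  }
  NULL
}

#' @export
print.ancestral_call <- function(x, ...) {
  cat("<ancestral_call: ", nrow(x$order), " genes from ",
    nrow(x$segments), " segment(s)>\n",
    sep = ""
  )
  print(x$order)
  invisible(x)
}

#' @export
tidy.ancestral_call <- function(x, ...) {
  tibble::tibble(
    segment = x$segments$segment,
    length = x$segments$length,
    provenance = x$segments$provenance,
    support = vapply(
      x$segments$support,
      function(s) paste(s, collapse = ","), character(1)
    )
  )
}

#' @export
glance.ancestral_call <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$order),
    n_segments = nrow(x$segments),
    shared_with_outgroup = sum(x$segments$provenance == "shared-with-outgroup"),
    shared_within_ingroup = sum(x$segments$provenance == "shared-within-ingroup"),
    defaulted = sum(x$segments$provenance == "defaulted-to-outgroup")
  )
}
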