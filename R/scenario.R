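#' Infer a rearrangement scenario between two gene orders
#'
#' Reconstructs an ordered list of rearrangement operations (inversions,
#' transpositions, inverse transpositions, TDRLs) transforming `source` into
#' `target`, from the strong interval tree of the common intervals between
#' the two orders (the heuristic popularized by the Common Interval
#' Rearrangement Explorer). The scenario is assembled forward from the
#' source:
#'
#' * a node whose content is the exact reversal of the sorted block becomes
#'   one inversion;
#' * a two-child block-exchange node becomes a transposition, or an inverse
#'   transposition when the displaced block is inverted (with a cheaper
#'   per-child inverse-transposition route when the larger child consists
#'   entirely of inverted sub-blocks in source order);
#' * inside prime (and unresolvable linear) nodes, runs of adjacent inverted
#'   children are rectified by single inversions, and the child blocks are
#'   then sorted by a minimal sequence of TDRLs (radix construction,
#'   `ceiling(log2(runs))` steps).
#'
#' Soundness is enforced: the composed operations are replayed on the source
#' and must reproduce the target exactly, else an internal error is raised.
#'
#' @param source,target Circular [gene_order()] objects over one gene set
#'   (`CR` is excluded from the permutation).
#' @param anchor Linearization anchor gene (default `"cob"`).
#' @return A `scenario` object: list with `ops` (list of operation records),
#'   `op_counts`, `source`, `target`, `anchor`.
#' @export
#' @examples
#' sc <- infer_scenario(
#'   reference_orders("ChalcidoidGO"),
#'   reference_orders("TrichogrammaGO")
#' )
#' glance(sc)
infer_scenario <- function(source, target, anchor = "cob") {
  .build_scenario(source, target, anchor, variant = list())
}

.build_scenario <- function(source, target, anchor, variant) {
  sp <- to_signed_permutation(target, source, anchor = anchor)
  n <- length(sp$perm)
  if (identical(sp$perm, seq_len(n))) {
    return(.new_scenario(list(), source, target, anchor))
  }
  tree <- strong_interval_tree(sp$perm)
  plan <- .emit_node(tree$root, sp$perm, variant)
  realized <- .realize_ops(plan, sp, variant)
  if (!identical(realized$state, sp$perm)) {
    stop("internal consistency failure: composed scenario does not reach the target",
      call. = FALSE
    )
  }
  sc <- .new_scenario(realized$ops, source, target, anchor)
  # independent gene-level replay
  out <- apply_scenario(source, sc)
  tgt_lin <- .linearized_genes(target, source, anchor)
  if (!all(out$gene == tgt_lin$gene) ||
    !all(out$orientation == tgt_lin$orientation)) {
    stop("internal consistency failure: gene-level replay does not reach the target",
      call. = FALSE
    )
  }
  sc
}

.new_scenario <- function(ops, source, target, anchor) {
  kinds <- vapply(ops, function(o) o$kind, character(1))
  structure(
    list(
      ops = ops,
      op_counts = c(
        inversion = sum(kinds == "inversion"),
        transposition = sum(kinds == "transposition"),
        inverse_transposition = sum(kinds == "inverse_transposition"),
        tdrl = sum(kinds == "tdrl")
      ),
      source = source, target = target, anchor = anchor
    ),
    class = "scenario"
  )
}

# ---- planning (value space) -------------------------------------------------

# Abstract op records operate on sets of values; they are realized against a
# running state later. Kinds: inv(values), move(values, invert, before/after),
# tdrl(units = list of value vectors, target_order).

.node_content <- function(node, perm) {
  pos <- integer(length(perm))
  pos[abs(perm)] <- seq_along(perm)
  idx <- sort(pos[node$a:node$b])
  perm[idx]
}

.is_sorted_forward <- function(node, perm) {
  identical(.node_content(node, perm), as.integer(node$a:node$b))
}

.is_fully_inverted <- function(node, perm) {
  identical(.node_content(node, perm), as.integer(-(node$b:node$a)))
}

.emit_node <- function(node, perm, variant) {
  if (.is_sorted_forward(node, perm)) {
    return(list())
  }
  if (.is_fully_inverted(node, perm)) {
    return(list(list(op = "inv", values = node$a:node$b)))
  }
  if (node$type == "leaf") {
    stop("internal error: unhandled leaf state", call. = FALSE)
  }
  if (node$type == "linear_inc") {
    return(do.call(c, lapply(node$children, .emit_node, perm = perm, variant = variant)))
  }
  kids <- node$children[order(vapply(node$children, function(ch) ch$a, integer(1)))]
  if (node$type == "linear_dec") {
    return(.emit_dec(kids, perm, variant))
  }
  .emit_prime(kids, perm, variant)
}

# Linear-decreasing node: the children (ascending value ranges c1..ck) appear
# in reverse order in the permutation. Dynamic program over contiguous child
# ranges, combining: whole-range inversion; peeling an end child off as a
# transposition; moving a maximal run of fully inverted children as one
# inverse transposition; per-child inverse transpositions out of an
# increasing child; and a TDRL fallback.
.emit_dec <- function(kids, perm, variant) {
  k <- length(kids)
  memo <- new.env(parent = emptyenv())
  rng <- function(i, j) kids[[i]]$a:kids[[j]]$b
  inv_flag <- vapply(kids, .is_fully_inverted, logical(1), perm = perm)
  plan <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    if (i == j) {
      res <- .emit_node(kids[[i]], perm, variant)
      memo[[key]] <- res
      return(res)
    }
    routes <- list()
    if (all(inv_flag[i:j])) {
      routes$inv <- list(list(op = "inv", values = rng(i, j)))
    }
    # transposition peels from either end
    routes$peel_lo <- c(
      list(list(
        op = "move", values = rng(i + 1, j), invert = FALSE,
        dest = "before", ref = rng(i, i)
      )),
      .emit_node(kids[[i]], perm, variant),
      plan(i + 1, j)
    )
    routes$peel_hi <- c(
      list(list(
        op = "move", values = rng(j, j), invert = FALSE,
        dest = "before", ref = rng(i, j - 1)
      )),
      .emit_node(kids[[j]], perm, variant),
      plan(i, j - 1)
    )
    # a maximal run of fully inverted children moves as one inverse
    # transposition (prefix run goes after the rest, suffix run before it)
    if (inv_flag[i]) {
      m <- i
      while (m < j && inv_flag[m + 1]) m <- m + 1
      if (m < j) {
        routes$ivt_lo <- c(
          list(list(
            op = "move", values = rng(i, m), invert = TRUE,
            dest = "after", ref = rng(m + 1, j)
          )),
          plan(m + 1, j)
        )
      }
    }
    if (inv_flag[j]) {
      m <- j
      while (m > i && inv_flag[m - 1]) m <- m - 1
      if (m > i) {
        routes$ivt_hi <- c(
          list(list(
            op = "move", values = rng(m, j), invert = TRUE,
            dest = "before", ref = rng(i, m - 1)
          )),
          plan(i, m - 1)
        )
      }
    }
    if (j - i == 1) {
      routes$stacked_hi <- .stacked_route(kids[[j]], kids[[i]], perm,
        after_sibling = FALSE, variant = variant
      )
      routes$stacked_lo <- .stacked_route(kids[[i]], kids[[j]], perm,
        after_sibling = TRUE, variant = variant
      )
    }
    routes$prime <- .emit_prime(kids[i:j], perm, variant)
    routes <- routes[!vapply(routes, is.null, logical(1))]
    costs <- vapply(routes, length, integer(1))
    pick <- names(routes)[which.min(costs)]
    if (isTRUE(variant$exchange_alt)) {
      co <- which(costs == min(costs))
      if (length(co) > 1) pick <- names(routes)[co[2]]
    }
    res <- routes[[pick]]
    memo[[key]] <- res
    res
  }
  plan(1, k)
}

# per-child inverse transpositions: `mover` must be a linear-increasing node
# whose children are all fully inverted; they are peeled off one by one and
# re-inserted, inverted, on the far side of `sib`
.stacked_route <- function(mover, sib, perm, after_sibling, variant) {
  if (mover$type != "linear_inc" || length(mover$children) < 2) {
    return(NULL)
  }
  kids <- mover$children[order(vapply(mover$children, function(ch) ch$a, integer(1)))]
  if (!all(vapply(kids, .is_fully_inverted, logical(1), perm = perm))) {
    return(NULL)
  }
  ops <- list()
  for (j in seq_along(kids)) {
    d <- kids[[j]]
    ops[[j]] <- list(
      op = "move", values = d$a:d$b, invert = TRUE,
      dest = if (j == 1 && !after_sibling) "before" else "after",
      ref = if (j == 1) sib$a:sib$b else (kids[[j - 1]]$a:kids[[j - 1]]$b)
    )
  }
  c(ops, .emit_node(sib, perm, variant))
}

.tdrl_steps_for <- function(cur_keys, target_keys) {
  if (identical(cur_keys, target_keys)) {
    return(0L)
  }
  r <- max(value_runs(match(cur_keys, target_keys)))
  if (r <= 1) 0L else as.integer(ceiling(log2(r)))
}

.emit_prime <- function(kids, perm, variant) {
  inv_flag <- vapply(kids, .is_fully_inverted, logical(1), perm = perm)
  pos <- integer(length(perm))
  pos[abs(perm)] <- seq_along(perm)
  kid_pos <- vapply(kids, function(ch) min(pos[ch$a:ch$b]), numeric(1))
  key <- function(u) paste(u[1], u[length(u)])

  ops <- list()
  for (j in seq_along(kids)) {
    if (!inv_flag[j]) ops <- c(ops, .emit_node(kids[[j]], perm, variant))
  }

  # sign-pass groups: maximal runs of value-adjacent fully inverted children
  grp <- rle(inv_flag)
  ends <- cumsum(grp$lengths)
  starts <- ends - grp$lengths + 1L
  groups <- list() # each: list(idx, inverted)
  for (g in seq_along(grp$values)) {
    groups[[g]] <- list(idx = starts[g]:ends[g], inverted = grp$values[g])
  }

  # candidate extractions: an inverted group whose members sit consecutively
  # (in reverse value order) in the permutation moves as one inverse
  # transposition; a positive child (or value-adjacent ascending run that is
  # consecutive in the permutation) moves as one transposition
  target_order <- order(kid_pos)
  rank_in_target <- match(seq_along(kids), target_order)
  extract <- list() # list of list(idx, invert)
  is_extracted <- rep(FALSE, length(kids))

  consec_in_target <- function(idx, reversed) {
    rks <- rank_in_target[idx]
    want <- if (reversed) rev(seq_along(idx)) - 1L else seq_along(idx) - 1L
    all(rks == min(rks) + want)
  }
  remaining_units <- function() {
    cur <- character(0)
    for (g in groups) {
      idx <- g$idx[!is_extracted[g$idx]]
      if (length(idx) == 0) next
      if (g$inverted) idx <- rev(idx)
      cur <- c(cur, vapply(idx, function(i) key(kids[[i]]$a:kids[[i]]$b), character(1)))
    }
    keep <- target_order[!is_extracted[target_order]]
    tgt <- vapply(keep, function(i) key(kids[[i]]$a:kids[[i]]$b), character(1))
    list(cur = cur, tgt = tgt)
  }
  cand_sets <- list()
  for (g in groups) {
    if (g$inverted && consec_in_target(g$idx, reversed = TRUE)) {
      cand_sets[[length(cand_sets) + 1]] <- list(
        idx = g$idx, invert = TRUE, save = 1L
      )
    }
    if (!g$inverted) {
      for (i in g$idx) {
        cand_sets[[length(cand_sets) + 1]] <- list(
          idx = i, invert = FALSE, save = 0L
        )
      }
    }
  }
  repeat {
    u <- remaining_units()
    base_steps <- .tdrl_steps_for(u$cur, u$tgt)
    best <- NULL
    best_gain <- 0L
    for (cs in cand_sets) {
      if (any(is_extracted[cs$idx])) next
      if (sum(!is_extracted) - length(cs$idx) < 1) next
      is_extracted[cs$idx] <- TRUE
      u2 <- remaining_units()
      is_extracted[cs$idx] <- FALSE
      gain <- base_steps - .tdrl_steps_for(u2$cur, u2$tgt) + cs$save - 1L
      if (gain > best_gain) {
        best_gain <- gain
        best <- cs
      }
    }
    if (is.null(best)) break
    is_extracted[best$idx] <- TRUE
    extract[[length(extract) + 1]] <- best
  }

  # inversions for the remaining inverted groups
  cur_units <- list()
  for (g in groups) {
    idx <- g$idx[!is_extracted[g$idx]]
    if (length(idx) == 0) next
    if (g$inverted) {
      lo <- kids[[idx[1]]]$a
      hi <- kids[[idx[length(idx)]]]$b
      ops <- c(ops, list(list(op = "inv", values = lo:hi)))
      idx <- rev(idx)
    }
    cur_units <- c(cur_units, lapply(idx, function(i) kids[[i]]$a:kids[[i]]$b))
  }
  target_units <- lapply(
    target_order[!is_extracted[target_order]],
    function(i) kids[[i]]$a:kids[[i]]$b
  )
  riders <- lapply(extract, function(cs) {
    range(unlist(lapply(cs$idx, function(i) c(kids[[i]]$a, kids[[i]]$b))))
  })
  riders <- lapply(riders, function(r) r[1]:r[2])
  if (!identical(
    vapply(cur_units, key, character(1)),
    vapply(target_units, key, character(1))
  ) || length(riders) > 0) {
    ops <- c(ops, list(list(
      op = "tdrl_phase", units = cur_units, target = target_units,
      riders = riders
    )))
  }
  # place extracted units at their final slots, left to right in the target
  if (length(extract) > 0) {
    first_rank <- vapply(
      extract,
      function(cs) min(rank_in_target[cs$idx]), integer(1)
    )
    for (e in extract[order(first_rank)]) {
      rks <- rank_in_target[e$idx]
      vals <- range(unlist(lapply(e$idx, function(i) c(kids[[i]]$a, kids[[i]]$b))))
      vals <- vals[1]:vals[2]
      before_rank <- min(rks) - 1L
      if (before_rank >= 1) {
        prev_kid <- kids[[target_order[before_rank]]]
        ops <- c(ops, list(list(
          op = "move", values = vals, invert = e$invert,
          dest = "after", ref = prev_kid$a:prev_kid$b
        )))
      } else {
        nxt_kid <- kids[[target_order[max(rks) + 1L]]]
        ops <- c(ops, list(list(
          op = "move", values = vals, invert = e$invert,
          dest = "before", ref = nxt_kid$a:nxt_kid$b
        )))
      }
    }
  }
  ops
}

# ---- realization ------------------------------------------------------------

# Applies planned ops to the identity state, recording concrete, gene-level
# operation records as each op is applied.
.realize_ops <- function(plan, sp, variant) {
  state <- seq_len(length(sp$perm))
  ops <- list()
  tok <- function(vals) { # signed tokens as read in the current state
    i <- match(vals, abs(state))
    i <- sort(i)
    list(
      genes = sp$genes[abs(state[i])],
      orientation = sign(state[i]) * sp$ref_orientation[abs(state[i])]
    )
  }
  locate <- function(vals) {
    i <- sort(match(vals, abs(state)))
    if (anyNA(i) || any(diff(i) != 1)) {
      stop("internal error: op block not contiguous", call. = FALSE)
    }
    i
  }
  for (op in plan) {
    if (op$op == "inv") {
      i <- locate(op$values)
      blk <- tok(op$values)
      ops[[length(ops) + 1]] <- list(
        kind = "inversion",
        genes = blk$genes, orientation = blk$orientation
      )
      state[i] <- -rev(state[i])
    } else if (op$op == "move") {
      i <- locate(op$values)
      blk <- tok(op$values)
      ref_i <- locate(op$ref)
      ref_first <- sp$genes[abs(state[ref_i[1]])]
      ref_last <- sp$genes[abs(state[ref_i[length(ref_i)]])]
      moved <- state[i]
      if (op$invert) moved <- -rev(moved)
      rest <- state[-i]
      jj <- sort(match(op$ref, abs(rest)))
      at <- if (op$dest == "before") min(jj) - 1L else max(jj)
      state <- append(rest, moved, after = at)
      ops[[length(ops) + 1]] <- list(
        kind = if (op$invert) "inverse_transposition" else "transposition",
        genes = blk$genes, orientation = blk$orientation,
        dest = op$dest,
        ref_gene = if (op$dest == "before") ref_first else ref_last
      )
    } else if (op$op == "tdrl_phase") {
      span_vals <- sort(unlist(c(op$units, op$riders)))
      # label every value by the target rank of its child unit; rider blocks
      # (units extracted as later moves) inherit a neighbour's label so they
      # stay glued to it through every duplication-loss step
      lab_of_value <- integer(max(span_vals))
      for (l in seq_along(op$target)) lab_of_value[op$target[[l]]] <- l
      unit_labels <- function() {
        i <- locate(span_vals)
        labs <- lab_of_value[abs(state[i])]
        if (any(labs == 0L)) {
          for (t in seq_along(labs)) {
            if (labs[t] == 0L && t > 1) labs[t] <- labs[t - 1]
          }
          for (t in rev(seq_along(labs))) {
            if (labs[t] == 0L && t < length(labs)) labs[t] <- labs[t + 1]
          }
        }
        list(i = i, labs = labs, seq = rle(labs)$values)
      }
      cu <- unit_labels()
      c_seq <- cu$seq
      if (!identical(sort(c_seq), seq_along(op$units))) {
        stop("internal error: child units scrambled before TDRL phase", call. = FALSE)
      }
      labels <- .tdrl_labels_for(c_seq, variant)
      steps <- tdrl_sort(c_seq, labels = labels)
      for (st in steps) {
        cu <- unit_labels()
        keep_by_label <- stats::setNames(st$keep, st$before)
        keep_elem <- unname(keep_by_label[as.character(cu$labs)])
        blk <- state[cu$i]
        ops[[length(ops) + 1]] <- list(
          kind = "tdrl",
          genes = sp$genes[abs(blk)],
          orientation = sign(blk) * sp$ref_orientation[abs(blk)],
          keep = keep_elem
        )
        state[cu$i] <- apply_tdrl(blk, keep_elem)
      }
    } else {
      stop("internal error: unknown planned op ", op$op, call. = FALSE)
    }
  }
  list(state = state, ops = ops)
}

# Alternative minimal TDRL labelings: when the run count r is below the next
# power of two there is slack in the radix labels; `variant$tdrl_skip` picks
# which label values to leave unused (default: the trailing ones).
.tdrl_labels_for <- function(c_seq, variant) {
  if (is.null(variant$tdrl_skip)) {
    return(NULL)
  }
  r <- max(value_runs(c_seq))
  if (r <= 1) {
    return(NULL)
  }
  pool <- 0:(2^ceiling(log2(r)) - 1)
  slack <- length(pool) - r
  if (slack == 0) {
    return(NULL)
  }
  s <- variant$tdrl_skip
  if (s + slack - 1 > length(pool)) {
    return(NULL)
  }
  pool[-(s:(s + slack - 1))]
}

# ---- gene-level application -------------------------------------------------

.linearized_genes <- function(order, reference, anchor) {
  sp <- to_signed_permutation(order, reference, anchor)
  tibble::tibble(
    gene = sp$genes[abs(sp$perm)],
    orientation = as.integer(sign(sp$perm) * sp$ref_orientation[abs(sp$perm)])
  )
}

#' Apply a scenario to a gene order
#'
#' Replays the operation records of a [infer_scenario()] result (or a
#' simulated ground-truth scenario) on `source`. Operations are located by
#' their gene content; an operation whose block is absent or non-contiguous
#' raises an error.
#'
#' @param source A circular [gene_order()].
#' @param scenario A `scenario` object.
#' @return A tibble (`gene`, `orientation`): the transformed order,
#'   linearized at the scenario's anchor.
#' @export
apply_scenario <- function(source, scenario) {
  sp <- to_signed_permutation(drop_cr(source), drop_cr(source), scenario$anchor)
  st <- tibble::tibble(
    gene = sp$genes,
    orientation = as.integer(sp$ref_orientation)
  )
  for (op in scenario$ops) {
    st <- .apply_op(st, op)
  }
  st
}

.apply_op <- function(st, op) {
  i <- match(op$genes, st$gene)
  if (anyNA(i)) {
    stop("operation references absent gene(s): ",
      paste(op$genes[is.na(i)], collapse = ", "),
      call. = FALSE
    )
  }
  i <- sort(i)
  if (any(diff(i) != 1)) {
    stop("operation block is not contiguous in the current order", call. = FALSE)
  }
  if (op$kind == "inversion") {
    st$gene[i] <- rev(st$gene[i])
    st$orientation[i] <- -rev(st$orientation[i])
    return(st)
  }
  if (op$kind %in% c("transposition", "inverse_transposition")) {
    blk <- st[i, ]
    if (op$kind == "inverse_transposition") {
      blk <- blk[rev(seq_len(nrow(blk))), ]
      blk$orientation <- -blk$orientation
    }
    rest <- st[-i, ]
    j <- match(op$ref_gene, rest$gene)
    if (is.na(j)) stop("destination gene absent: ", op$ref_gene, call. = FALSE)
    at <- if (op$dest == "before") j - 1L else j
    out <- dplyr::bind_rows(
      rest[seq_len(at), ],
      blk,
      if (at < nrow(rest)) rest[(at + 1):nrow(rest), ]
    )
    return(out)
  }
  if (op$kind == "tdrl") {
    keep <- op$keep
    reord <- c(i[keep == 1L], i[keep == 2L])
    st[i, ] <- st[reord, ]
    return(st)
  }
  stop("unknown operation kind: ", op$kind, call. = FALSE)
}

# ---- enumeration ------------------------------------------------------------

#' Enumerate co-optimal rearrangement scenarios
#'
#' Generates distinct scenarios of equal operation count by exercising the
#' documented tie-points of the heuristic: alternative minimal TDRL
#' labelings (the radix construction has slack when the run count is not a
#' power of two) and equal-cost block-exchange interpretations. Every
#' returned scenario passes the soundness check.
#'
#' @inheritParams infer_scenario
#' @param limit Maximum number of scenarios to return.
#' @return A list of `scenario` objects, all of equal length.
#' @export
enumerate_scenarios <- function(source, target, anchor = "cob", limit = 5) {
  base <- infer_scenario(source, target, anchor)
  out <- list(base)
  seen <- .scenario_key(base)
  if (base$op_counts["tdrl"] > 0) {
    for (s in seq_len(limit * 4)) {
      if (length(out) >= limit) break
      sc <- tryCatch(
        .build_scenario(source, target, anchor, variant = list(tdrl_skip = s)),
        error = function(e) NULL
      )
      if (is.null(sc)) next
      if (length(sc$ops) != length(base$ops)) next
      k <- .scenario_key(sc)
      if (!k %in% seen) {
        out[[length(out) + 1]] <- sc
        seen <- c(seen, k)
      }
    }
  }
  if (length(out) < limit) {
    sc <- tryCatch(
      .build_scenario(source, target, anchor, variant = list(exchange_alt = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(sc) && length(sc$ops) == length(base$ops)) {
      k <- .scenario_key(sc)
      if (!k %in% seen) out[[length(out) + 1]] <- sc
    }
  }
  out
}

.scenario_key <- function(sc) {
  paste(vapply(sc$ops, function(o) {
    paste(o$kind, paste(o$genes, collapse = ","),
      paste(o$orientation, collapse = ","),
      paste(o$keep %||% "", collapse = ""),
      sep = "|"
    )
  }, character(1)), collapse = ";")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario: ", length(x$ops), " operation(s), anchor ", x$anchor, ">\n", sep = "")
  cat(scenario_narrative(x), sep = "\n")
  invisible(x)
}

#' Plain-text narrative of a scenario
#'
#' @param scenario A `scenario` object.
#' @return Character vector, one line per operation.
#' @export
scenario_narrative <- function(scenario) {
  if (length(scenario$ops) == 0) {
    return("no operations: orders are identical")
  }
  vapply(seq_along(scenario$ops), function(i) {
    op <- scenario$ops[[i]]
    blk <- paste0(
      ifelse(op$orientation < 0, "-", ""), .short_label(op$genes),
      collapse = " "
    )
    desc <- switch(op$kind,
      inversion = paste0("inversion of [", blk, "]"),
      transposition = paste0(
        "transposition of [", blk, "] to ",
        op$dest, " ", .short_label(op$ref_gene)
      ),
      inverse_transposition = paste0(
        "inverse transposition of [", blk, "] to ",
        op$dest, " ", .short_label(op$ref_gene)
      ),
      tdrl = paste0(
        "tandem duplication-random loss over [", blk, "], keeping copies (",
        paste(op$keep, collapse = ""), ")"
      )
    )
    sprintf("operation %d: %s", i, desc)
  }, character(1))
}

#' @export
tidy.scenario <- function(x, ...) {
  if (length(x$ops) == 0) {
    return(tibble::tibble(
      step = integer(), kind = character(), genes = character(), span = integer()
    ))
  }
  tibble::tibble(
    step = seq_along(x$ops),
    kind = vapply(x$ops, function(o) o$kind, character(1)),
    genes = vapply(x$ops, function(o) {
      paste0(ifelse(o$orientation < 0, "-", ""), o$genes, collapse = " ")
    }, character(1)),
    span = vapply(x$ops, function(o) length(o$genes), integer(1))
  )
}

#' @export
glance.scenario <- function(x, ...) {
  tibble::tibble(
    n_ops = length(x$ops),
    inversions = unname(x$op_counts["inversion"]),
    transpositions = unname(x$op_counts["transposition"]),
    inverse_transpositions = unname(x$op_counts["inverse_transposition"]),
    tdrls = unname(x$op_counts["tdrl"]),
    anchor = x$anchor
  )
}
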