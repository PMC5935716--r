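# Independent brute-force oracles, written against the definitions (not the
# package implementations) and kept deliberately naive.

# all common intervals [a, b] (b > a) of a signed permutation vs identity:
# positions of values a..b, located one by one, must form a contiguous block
oracle_common_intervals <- function(perm) {
  p <- abs(as.integer(perm))
  n <- length(p)
  out <- matrix(integer(0), ncol = 2)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      where <- which(p %in% a:b)
      if (max(where) - min(where) + 1 == b - a + 1) {
        out <- rbind(out, c(a, b))
      }
    }
  }
  out
}

# strong = crossing no other common interval; singletons and [1, n] added
oracle_strong_intervals <- function(perm) {
  n <- length(perm)
  ci <- oracle_common_intervals(perm)
  cand <- unique(rbind(ci, cbind(1:n, 1:n), c(1L, n)))
  strong <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]
    b <- cand[i, 2]
    ok <- TRUE
    for (j in seq_len(nrow(ci))) {
      c <- ci[j, 1]
      d <- ci[j, 2]
      overlap <- max(a, c) <= min(b, d)
      nested <- (a <= c && d <= b) || (c <= a && b <= d)
      if (overlap && !nested) {
        ok <- FALSE
        break
      }
    }
    strong[i] <- ok
  }
  out <- cand[strong, , drop = FALSE]
  out[order(out[, 1], -out[, 2]), , drop = FALSE]
}

# exact minimal TDRL distance to the identity for every permutation of 1..n:
# build the full move graph (sigma -> every stable binary partition of sigma)
# over the symmetric group, then breadth-first search on reversed edges from
# the identity
oracle_tdrl_distances <- function(n) {
  perms <- .all_perms(n)
  key <- vapply(perms, paste, character(1), collapse = ",")
  idx <- stats::setNames(seq_along(perms), key)
  masks <- lapply(0:(2^n - 1), function(m) bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_along(perms)) {
    p <- perms[[i]]
    succ <- unique(vapply(
      masks,
      function(bits) paste(c(p[!bits], p[bits]), collapse = ","),
      character(1)
    ))
    from <- c(from, rep.int(i, length(succ)))
    to <- c(to, unname(idx[succ]))
  }
  preds <- split(from, to)
  dist <- rep(NA_integer_, length(perms))
  id <- idx[[paste(seq_len(n), collapse = ",")]]
  dist[id] <- 0L
  frontier <- id
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(unlist(preds[as.character(frontier)]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  stats::setNames(dist, key)
}

.all_perms <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  sub <- .all_perms(n - 1)
  out <- list()
  for (p in sub) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- as.integer(append(p, n, after = k))
    }
  }
  out
}

# breakpoint distance by direct enumeration of extremity pairs
oracle_breakpoint <- function(a, b) {
  pairs <- function(o) {
    o <- drop_cr(o)
    n <- nrow(o)
    out <- character(n)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      e1 <- paste0(o$gene[i], ".", if (o$orientation[i] > 0) "h" else "t")
      e2 <- paste0(o$gene[j], ".", if (o$orientation[j] > 0) "t" else "h")
      out[i] <- paste(sort(c(e1, e2)), collapse = "|")
    }
    out
  }
  length(setdiff(pairs(a), pairs(b)))
}

# random signed circular order over a sample of the real gene vocabulary
random_order <- function(n = 10, seed = NULL, name = "random") {
  if (!is.null(seed)) set.seed(seed)
  vocab <- gene_vocabulary()
  genes <- sample(vocab$gene[vocab$class != "CR"], n)
  gene_order(sample(genes), sample(c(-1L, 1L), n, replace = TRUE), name = name)
}

tj_table <- function() {
  read_annotation_tsv(mitorearr_example("tjaponicum_annotation.tsv"))
}

to_table <- function() {
  read_annotation_tsv(mitorearr_example("tostriniae_annotation.tsv"))
}
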