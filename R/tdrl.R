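#' Minimal TDRL sorting of an unsigned permutation
#'
#' A tandem-duplication-random-loss (TDRL) step duplicates the whole region
#' and keeps, for every element, exactly one copy; the result is the kept
#' first-copy elements in order followed by the kept second-copy elements.
#' The minimum number of TDRLs sorting a positive permutation to the
#' identity is `ceiling(log2(r))`, where `r` is the number of maximal runs
#' of consecutive values with increasing positions. The construction is a
#' radix sort on run index: step `j` keeps elements whose run index has bit
#' `j` unset in the first copy.
#'
#' @param perm A positive (unsigned) permutation of `1..n`.
#' @param labels Optional run labels (ascending integers, one per run,
#'   `0`-based and below `2^ceiling(log2(r))`); used to enumerate
#'   alternative minimal sorting sequences. Default `0:(r-1)`.
#' @return A list of steps; each step is a list with `keep` (integer vector
#'   of 1/2 per element, in the order of the current arrangement before the
#'   step) and `before`/`after` (the arrangements around the step).
#' @export
#' @examples
#' tdrl_sort(c(4L, 3L, 2L, 1L)) # 2 steps
tdrl_sort <- function(perm, labels = NULL) {
  p <- as.integer(perm)
  if (any(p < 0)) {
    stop("tdrl_sort() requires an unsigned (all-positive) permutation",
      call. = FALSE
    )
  }
  if (!identical(sort(p), seq_along(p))) {
    stop("not a permutation of 1..n", call. = FALSE)
  }
  rid <- value_runs(p)
  r <- max(rid)
  if (r == 1) {
    return(list())
  }
  nbits <- ceiling(log2(r))
  labels <- labels %||% (seq_len(r) - 1L)
  if (length(labels) != r || is.unsorted(labels, strictly = TRUE) ||
    any(labels < 0) || any(labels >= 2^nbits)) {
    stop("labels must be ", r, " ascending integers in [0, ", 2^nbits - 1, "]",
      call. = FALSE
    )
  }
  lab <- labels[rid] # per-value run label
  cur <- p
  steps <- list()
  for (j in seq_len(nbits) - 1L) {
    bit <- bitwAnd(lab[cur], 2^j) > 0
    keep <- ifelse(bit, 2L, 1L)
    nxt <- c(cur[!bit], cur[bit])
    if (!identical(nxt, cur)) {
      steps[[length(steps) + 1]] <- list(keep = keep, before = cur, after = nxt)
      cur <- nxt
    }
  }
  if (!identical(cur, seq_along(p))) {
    stop("internal error: TDRL radix sort failed", call. = FALSE)
  }
  steps
}

#' Run index of each value of a positive permutation
#'
#' Values `v` and `v+1` belong to the same run when `v+1` occurs after `v`
#' in the permutation.
#'
#' @param perm Positive permutation.
#' @return Integer vector `rid` where `rid[v]` is the 1-based run index of
#'   value `v`; `max(rid)` is the run count `r`.
#' @export
value_runs <- function(perm) {
  p <- as.integer(perm)
  n <- length(p)
  pos <- integer(n)
  pos[p] <- seq_len(n)
  if (n == 1) {
    return(1L)
  }
  breaks <- pos[-1] < pos[-n] # break between v and v+1
  cumsum(c(1L, as.integer(breaks)))
}

#' Apply one TDRL step to a sequence
#'
#' @param x A vector (the region).
#' @param keep Integer vector of 1/2, one per element of `x`.
#' @return The rearranged vector: kept-first-copy elements then
#'   kept-second-copy elements, each in original order.
#' @export
apply_tdrl <- function(x, keep) {
  stopifnot(length(keep) == length(x), all(keep %in% 1:2))
  c(x[keep == 1L], x[keep == 2L])
}
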