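#' Find tandem repeats by per-period dynamic scanning
#'
#' A self-contained scan: for every candidate unit length `p` the sequence is
#' compared against itself at lag `p`; maximal matching runs (optionally
#' bridged across isolated mismatches up to `max_mismatch_fraction` of the
#' repeat span) become repeat hits of fractional copy number
#' `span / p`. Hits nested inside an equal-or-better hit (same or larger
#' span with a shorter unit) are removed, so a perfect `(TA)40` is reported
#' once with unit length 2, not also at lags 4, 6, ...
#'
#' @param seq A single nucleotide string.
#' @param min_unit,max_unit Unit-length range in bp.
#' @param min_copies Minimum (fractional) copy number to report.
#' @param max_mismatch_fraction Allowed mismatch fraction when bridging
#'   interrupted repeats (0 = perfect repeats only).
#' @return A tibble: `unit` (consensus = first copy), `unit_length`,
#'   `copies`, `start`, `end`, `mismatches`, sorted by position.
#' @export
#' @examples
#' find_tandem_repeats(strrep("AGCCTCAAAAATCGGGGTTTT", 3), min_unit = 10)
find_tandem_repeats <- function(seq, min_unit = 1, max_unit = 60,
                                min_copies = 2, max_mismatch_fraction = 0) {
  s <- charToRaw(toupper(as.character(seq)))
  L <- length(s)
  max_unit <- min(max_unit, floor(L / max(min_copies, 1)))
  hits <- list()
  for (p in seq(from = min_unit, length.out = max(0, max_unit - min_unit + 1))) {
    if (L < 2 * p) break
    m <- s[seq_len(L - p)] == s[seq_len(L - p) + p]
    runs <- rle(m)
    if (!any(runs$values)) next
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    seg <- data.frame(
      start = starts[runs$values], end = ends[runs$values],
      mm = 0L
    )
    # bridge across mismatches while the mismatch fraction stays in budget
    if (max_mismatch_fraction > 0 && nrow(seg) > 1) {
      i <- 1
      while (i < nrow(seg)) {
        gap <- seg$start[i + 1] - seg$end[i] - 1L
        mm <- seg$mm[i] + seg$mm[i + 1] + gap
        span <- seg$end[i + 1] + p - seg$start[i]
        if (mm / span <= max_mismatch_fraction) {
          seg$end[i] <- seg$end[i + 1]
          seg$mm[i] <- mm
          seg <- seg[-(i + 1), , drop = FALSE]
        } else {
          i <- i + 1
        }
      }
    }
    span <- seg$end + p - seg$start
    keep <- span / p >= min_copies
    if (!any(keep)) next
    seg <- seg[keep, , drop = FALSE]
    hits[[length(hits) + 1]] <- tibble::tibble(
      unit_length = p,
      start = seg$start,
      end = seg$end + p,
      copies = (seg$end + p - seg$start + 1) / p,
      mismatches = seg$mm
    )
  }
  if (length(hits) == 0) {
    return(tibble::tibble(
      unit = character(), unit_length = integer(), copies = numeric(),
      start = integer(), end = integer(), mismatches = integer()
    ))
  }
  out <- dplyr::bind_rows(hits)
  # drop hits nested in an equal-or-longer span with a shorter unit
  n <- nrow(out)
  nested <- vapply(seq_len(n), function(i) {
    any(
      out$start <= out$start[i] & out$end >= out$end[i] &
        (out$unit_length < out$unit_length[i] |
          (out$unit_length == out$unit_length[i] &
            (out$end - out$start) > (out$end[i] - out$start[i])))
    )
  }, logical(1))
  out <- out[!nested, , drop = FALSE]
  seq_chr <- toupper(as.character(seq))
  out$unit <- substring(seq_chr, out$start, out$start + out$unit_length - 1)
  out <- dplyr::arrange(out, .data$start, .data$unit_length)
  dplyr::select(
    out, "unit", "unit_length", "copies", "start", "end", "mismatches"
  )
}
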