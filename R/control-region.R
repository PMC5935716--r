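#' Scan a control region for its conserved elements
#'
#' Reports the five element classes of insect mitochondrial control regions,
#' wherever they occur (order and position are not constrained):
#'
#' 1. a polyT stretch (>= `min_polyt` consecutive T),
#' 2. a `[TA(A)]n`-like stretch (>= `min_taa_units` consecutive TA/TAA units),
#' 3. a stem-loop (arm `stem_range`, loop `loop_range`, up to
#'    `stem_mismatch` mismatched arm pairs; the longest arm wins),
#' 4. a `TATA` motif and a `G(A)nT` motif (1 <= n <= `max_ga_n`),
#' 5. a G+A-rich segment (window >= `min_garich_len` with G+A fraction >=
#'    `garich_fraction`).
#'
#' @param seq A single nucleotide string.
#' @param min_polyt,min_taa_units,stem_range,loop_range,stem_mismatch,max_ga_n,min_garich_len,garich_fraction
#'   Detection thresholds (defaults documented above).
#' @return A tibble with columns `element`, `start`, `end`, `detail`;
#'   absent elements are simply absent from the table.
#' @export
#' @examples
#' scan_control_region("TTTTTTTATAATAATAAGGGCCCC")
scan_control_region <- function(seq,
                                min_polyt = 5,
                                min_taa_units = 3,
                                stem_range = c(5, 20),
                                loop_range = c(3, 30),
                                stem_mismatch = 1,
                                max_ga_n = 6,
                                min_garich_len = 10,
                                garich_fraction = 0.8) {
  s <- toupper(as.character(seq))
  rows <- list()
  add <- function(element, m, detail = NA_character_) {
    if (m$start[1] == -1) {
      return()
    }
    rows[[length(rows) + 1]] <<- tibble::tibble(
      element = element, start = m$start, end = m$start + m$len - 1,
      detail = if (is.na(detail)) substring(s, m$start, m$start + m$len - 1) else detail
    )
  }
  matches <- function(pattern) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1]]
    list(start = as.integer(m), len = attr(m, "match.length"))
  }

  add("polyT", matches(sprintf("T{%d,}", min_polyt)))
  add("TA(A)n", matches(sprintf("(?:TAA|TA){%d,}", min_taa_units)))
  add("TATA", matches("TATA"))
  add("G(A)nT", matches(sprintf("GA{1,%d}T", max_ga_n)))

  ga <- .garich_segments(s, min_garich_len, garich_fraction)
  if (nrow(ga) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      element = "GA-rich", start = ga$start, end = ga$end,
      detail = sprintf("%.0f%% G+A", 100 * ga$fraction)
    )
  }

  sl <- find_stem_loop(s,
    stem_range = stem_range, loop_range = loop_range,
    max_mismatch = stem_mismatch
  )
  if (!is.null(sl)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      element = "stem-loop", start = sl$start, end = sl$end,
      detail = sprintf(
        "arm %d bp, loop %d nt, %d mismatch(es)",
        sl$arm, sl$loop, sl$mismatches
      )
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      element = character(), start = integer(), end = integer(),
      detail = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}

# maximal segments with (G+A)/length >= fraction and length >= min_len,
# grown greedily from qualifying seed windows
.garich_segments <- function(s, min_len, fraction) {
  v <- strsplit(s, "")[[1]]
  ga <- as.integer(v %in% c("G", "A"))
  n <- length(ga)
  if (n < min_len) {
    return(tibble::tibble(start = integer(), end = integer(), fraction = numeric()))
  }
  cs <- c(0L, cumsum(ga))
  win <- cs[(min_len + 1):(n + 1)] - cs[1:(n - min_len + 1)]
  seed <- which(win / min_len >= fraction)
  if (length(seed) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), fraction = numeric()))
  }
  # merge overlapping/adjacent qualifying windows into segments
  segs <- list()
  cur_s <- seed[1]
  cur_e <- seed[1] + min_len - 1L
  for (i in seed[-1]) {
    if (i <= cur_e + 1L) {
      cur_e <- i + min_len - 1L
    } else {
      segs[[length(segs) + 1]] <- c(cur_s, cur_e)
      cur_s <- i
      cur_e <- i + min_len - 1L
    }
  }
  segs[[length(segs) + 1]] <- c(cur_s, cur_e)
  out <- do.call(rbind, segs)
  tibble::tibble(
    start = out[, 1], end = out[, 2],
    fraction = (cs[out[, 2] + 1] - cs[out[, 1]]) / (out[, 2] - out[, 1] + 1)
  )
}

#' Locate the best stem-loop (hairpin) in a sequence
#'
#' Exhaustive scan over arm lengths and loop sizes; arms must be reverse
#' complements up to `max_mismatch` mismatched pairs. The hit with the
#' longest arm (ties: fewest mismatches, then leftmost) is returned.
#'
#' @param seq Nucleotide string.
#' @param stem_range Two-element vector: min and max arm length (bp).
#' @param loop_range Two-element vector: min and max loop length (nt).
#' @param max_mismatch Allowed mismatched arm pairs.
#' @return A list (`start`, `end`, `arm`, `loop`, `mismatches`) or `NULL`.
#' @export
find_stem_loop <- function(seq, stem_range = c(5, 20), loop_range = c(3, 30),
                           max_mismatch = 1) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(s)
  best <- NULL
  arm_max <- min(stem_range[2], floor((n - loop_range[1]) / 2))
  if (arm_max < stem_range[1]) {
    return(NULL)
  }
  for (arm in seq(arm_max, stem_range[1])) {
    for (loop in seq(loop_range[1], loop_range[2])) {
      total <- 2 * arm + loop
      if (total > n) next
      starts <- seq_len(n - total + 1)
      mism <- integer(length(starts))
      for (k in seq_len(arm)) {
        left <- s[starts + k - 1]
        right <- s[starts + total - k]
        mism <- mism + as.integer(comp[left] != right | is.na(comp[left]))
      }
      ok <- which(mism <= max_mismatch)
      if (length(ok) > 0) {
        pick <- ok[which.min(mism[ok])]
        cand <- list(
          start = starts[pick], end = starts[pick] + total - 1,
          arm = arm, loop = loop, mismatches = mism[pick]
        )
        if (is.null(best) ||
          cand$arm > best$arm ||
          (cand$arm == best$arm && cand$mismatches < best$mismatches)) {
          best <- cand
        }
      }
    }
    if (!is.null(best) && best$arm >= arm) break # longer arms already tried
  }
  best
}
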