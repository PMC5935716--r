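#' Simulation configuration
#'
#' Bundles the seed, rearrangement parameters and sequence-composition
#' parameters for the synthetic-data generators. Defaults emulate a typical
#' chalcidoid mitochondrial genome: strongly A+T-biased composition with a
#' positive AT skew and negative GC skew on the majority strand.
#'
#' @param seed Integer seed; every generator call is reproducible from it.
#' @param base_order Base [gene_order()] (default `ChalcidoidGO`).
#' @param op_count Number of rearrangement operations to apply.
#' @param op_weights Named sampling weights for
#'   `inversion`/`transposition`/`inverse_transposition`/`tdrl`.
#' @param block_p Geometric parameter for block lengths (mean `1/block_p`).
#' @param genome_length Sequence length in bp.
#' @param at_content Target A+T percentage.
#' @param at_skew,gc_skew Target majority-strand skews.
#' @param repeats List of `list(unit=, copies=)` tandem repeats to embed in
#'   the control region.
#' @param cr_elements Embed the five control-region element classes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              base_order = reference_orders("ChalcidoidGO"),
                              op_count = 1L,
                              op_weights = c(
                                inversion = 1, transposition = 1,
                                inverse_transposition = 1, tdrl = 1
                              ),
                              block_p = 0.25,
                              genome_length = 16000L,
                              at_content = 84,
                              at_skew = 0.05,
                              gc_skew = -0.25,
                              repeats = list(),
                              cr_elements = TRUE) {
  stopifnot(
    all(op_weights >= 0), any(op_weights > 0),
    block_p > 0, block_p <= 1,
    at_content >= 0, at_content <= 100
  )
  structure(
    list(
      seed = as.integer(seed), base_order = base_order,
      op_count = as.integer(op_count), op_weights = op_weights,
      block_p = block_p, genome_length = as.integer(genome_length),
      at_content = at_content, at_skew = at_skew, gc_skew = gc_skew,
      repeats = repeats, cr_elements = cr_elements
    ),
    class = "simulation_config"
  )
}

#' Simulate a rearranged gene order with known history
#'
#' Applies `op_count` sampled operations to the base order (linearized at
#' its first gene; the anchor itself is never moved, so the ground truth is
#' expressed in a fixed frame). Sampled operations are conditioned on being
#' observable and diagnostic of their kind: no-ops are rejected, an inverse
#' transposition must actually displace its block, and a TDRL keep pattern
#' must not reduce to an identity or to a single block exchange (such
#' outcomes are indistinguishable from simpler operation kinds, so a
#' ground-truth label would be meaningless).
#'
#' @param config A [simulation_config()].
#' @return List with `derived` ([gene_order()]), `scenario` (ground-truth
#'   `scenario` object) and `base`.
#' @export
#' @examples
#' sim <- simulate_orders(simulation_config(seed = 7, op_count = 2))
#' sim$scenario$op_counts
simulate_orders <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  base <- drop_cr(config$base_order)
  anchor <- base$gene[1]
  st <- linearize(base, anchor)
  st <- tibble::tibble(gene = st$gene, orientation = st$orientation)
  kinds <- names(config$op_weights)
  ops <- list()
  for (k in seq_len(config$op_count)) {
    kind <- sample(kinds, 1, prob = config$op_weights)
    op <- .sample_op(st, kind, config$block_p)
    st <- .apply_op(st, op)
    ops[[k]] <- op
  }
  scenario <- .new_scenario(
    ops,
    source = config$base_order, target = NULL, anchor = anchor
  )
  derived <- gene_order(st$gene, st$orientation,
    name = "simulated", circular = TRUE
  )
  scenario$target <- derived
  list(derived = derived, scenario = scenario, base = config$base_order)
}

.sample_block <- function(n, block_p, min_len = 1) {
  len <- min_len + stats::rgeom(1, block_p)
  len <- min(len, n - 2L) # keep the anchor (position 1) fixed and leave room
  len <- max(len, min_len)
  start <- sample(2:(n - len + 1), 1)
  start:(start + len - 1L)
}

.sample_op <- function(st, kind, block_p) {
  n <- nrow(st)
  for (try in 1:200) {
    if (kind == "inversion") {
      idx <- .sample_block(n, block_p)
      return(list(
        kind = "inversion",
        genes = st$gene[idx], orientation = st$orientation[idx]
      ))
    }
    if (kind %in% c("transposition", "inverse_transposition")) {
      idx <- .sample_block(n, block_p)
      rest <- setdiff(seq_len(n), idx)
      # insertion slot: after one of the remaining genes (never in front of
      # the anchor), excluding the slot the block came from
      slots <- setdiff(rest, idx[1] - 1L)
      if (length(slots) == 0) next
      after <- sample(slots, 1)
      return(list(
        kind = kind,
        genes = st$gene[idx], orientation = st$orientation[idx],
        dest = "after", ref_gene = st$gene[after]
      ))
    }
    if (kind == "tdrl") {
      idx <- .sample_block(n, block_p, min_len = 5)
      keep <- sample(1:2, length(idx), replace = TRUE)
      if (length(rle(keep)$lengths) < 5) next # must be TDRL-diagnostic
      return(list(
        kind = "tdrl",
        genes = st$gene[idx], orientation = st$orientation[idx],
        keep = keep
      ))
    }
    stop("unknown op kind: ", kind, call. = FALSE)
  }
  stop("could not sample a valid ", kind, " after 200 attempts", call. = FALSE)
}

#' Simulate an annotated genome sequence with controlled composition
#'
#' Draws a sequence with exact base counts matching the target A+T content
#' and skews (counts are rounded, then shuffled), lays the 37 genes plus the
#' control region out along the molecule with configurable spacer sizes, and
#' embeds the requested tandem repeats and control-region elements at
#' recorded positions inside the control region.
#'
#' @param config A [simulation_config()].
#' @param feature_sizes Named sizes (bp) overriding the built-in defaults
#'   (tRNA 65, rRNA 780/1350, typical PCG sizes).
#' @param gaps Named integer vector: spacer (negative = overlap) inserted
#'   after the named gene; unnamed features abut.
#' @return List with `seq` (character), `table` (`annotation_table`) and
#'   `truth` (positions of embedded repeats/elements).
#' @export
simulate_genome <- function(config, feature_sizes = NULL, gaps = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  ord <- config$base_order
  if (!"CR" %in% ord$gene) {
    stop("base order must include CR for genome layout", call. = FALSE)
  }
  # CR last so it absorbs the remaining length
  ordl <- linearize(ord, ord$gene[(match("CR", ord$gene) %% nrow(ord)) + 1L])
  sizes <- .default_feature_sizes()
  if (!is.null(feature_sizes)) sizes[names(feature_sizes)] <- feature_sizes
  genes <- ordl$gene[ordl$gene != "CR"]
  gsz <- unname(sizes[genes])
  gap_after <- stats::setNames(rep(0L, length(genes)), genes)
  if (!is.null(gaps)) gap_after[names(gaps)] <- as.integer(gaps)
  start <- integer(length(genes))
  end <- integer(length(genes))
  pos <- 1L
  for (i in seq_along(genes)) {
    start[i] <- pos
    end[i] <- pos + gsz[i] - 1L
    pos <- end[i] + 1L + gap_after[[genes[i]]]
  }
  cr_start <- pos
  if (cr_start + 50L > config$genome_length) {
    stop("layout error: features exceed genome_length", call. = FALSE)
  }
  glen <- config$genome_length
  table <- annotation_table(
    genome_name = sprintf("simulated_%d", config$seed),
    gene = c(genes, "CR"),
    strand = c(ordl$orientation[ordl$gene != "CR"], 1L),
    start = c(start, cr_start),
    end = c(end, glen),
    genome_length = glen,
    circular = TRUE
  )
  seq <- .compose_sequence(glen, config$at_content, config$at_skew, config$gc_skew)
  truth <- list()
  at <- cr_start
  if (isTRUE(config$cr_elements)) {
    elements <- c(
      polyT = strrep("T", 8),
      taa = strrep("TAA", 4),
      stem_loop = paste0("GGCTTACAGG", strrep("A", 6), revcomp("GGCTTACAGG")),
      tata = "TATA",
      gant = "GAAAT",
      ga_rich = "GAGAAAGAGAAG"
    )
    for (nm in names(elements)) {
      el <- elements[[nm]]
      substr(seq, at, at + nchar(el) - 1L) <- el
      truth[[nm]] <- c(start = at, end = at + nchar(el) - 1L)
      at <- at + nchar(el) + 3L
    }
  }
  for (r in config$repeats) {
    block <- strrep(r$unit, r$copies)
    if (at + nchar(block) - 1L > glen) {
      stop("layout error: repeats exceed the control region", call. = FALSE)
    }
    substr(seq, at, at + nchar(block) - 1L) <- block
    truth[[paste0("repeat_", nchar(r$unit), "bp")]] <- c(
      start = at, end = at + nchar(block) - 1L,
      unit_length = nchar(r$unit), copies = r$copies
    )
    at <- at + nchar(block) + 5L
  }
  list(seq = seq, table = table, truth = truth)
}

.default_feature_sizes <- function() {
  vocab <- gene_vocabulary()
  pcg <- c(
    atp6 = 675, atp8 = 165, cob = 1140, cox1 = 1536, cox2 = 681,
    cox3 = 789, nad1 = 936, nad2 = 1011, nad3 = 354, nad4 = 1341,
    nad4l = 288, nad5 = 1683, nad6 = 525
  )
  trna <- stats::setNames(
    rep(65L, sum(vocab$class == "tRNA")),
    vocab$gene[vocab$class == "tRNA"]
  )
  c(pcg, trna, rrnS = 780L, rrnL = 1350L)
}

# exact-count composition: pA/pT from the AT target and skew, pG/pC likewise
.compose_sequence <- function(len, at_content, at_skew, gc_skew) {
  at <- at_content / 100
  pa <- at * (1 + at_skew) / 2
  pt <- at * (1 - at_skew) / 2
  pg <- (1 - at) * (1 + gc_skew) / 2
  pc <- (1 - at) * (1 - gc_skew) / 2
  counts <- round(len * c(A = pa, C = pc, G = pg, T = pt))
  while (sum(counts) < len) counts["A"] <- counts["A"] + 1L
  while (sum(counts) > len) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  paste(sample(rep(c("A", "C", "G", "T"), counts)), collapse = "")
}
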