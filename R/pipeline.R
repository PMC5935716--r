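#' Run an analysis stage and write its reports
#'
#' Single programmatic entry point tying the stages together; the thin
#' command-line wrapper installed under `exec/` forwards to this function.
#' Subcommands:
#'
#' * `stats` — annotation-table metrics (`inputs$annotation`, a TSV or
#'   GenBank path; optional `inputs$fasta` for sequence features).
#' * `compare` — rearrangement classification and breakpoint distance
#'   between `inputs$a` and `inputs$b` (gene-order files or registry names).
#' * `scenario` — rearrangement-scenario inference from `inputs$source` to
#'   `inputs$target`.
#' * `ancestral` — ancestral assembly from `inputs$ingroup` and
#'   `inputs$outgroup` (gene-order files).
#' * `simulate` — seeded gene-order and genome simulation.
#'
#' @param subcommand One of `"stats"`, `"compare"`, `"scenario"`,
#'   `"ancestral"`, `"simulate"`.
#' @param inputs Named list of input paths or registry names (see above).
#' @param out_dir Output directory for JSON/TSV reports (created if needed);
#'   `NULL` suppresses writing.
#' @param seed Seed recorded in the run log and used by `simulate`.
#' @param options Named list of stage options (thresholds, anchor, rule);
#'   unknown keys are rejected.
#' @return The stage result (list), invisibly when reports are written.
#' @export
run_pipeline <- function(subcommand, inputs = list(), out_dir = NULL,
                         seed = 1L, options = list()) {
  subcommand <- match.arg(
    subcommand,
    c("stats", "compare", "scenario", "ancestral", "simulate")
  )
  known <- c(
    "anchor", "rule", "min_len", "min_ingroup_support", "op_count",
    "include_cr", "min_unit", "max_unit", "min_copies", "max_mismatch_fraction"
  )
  bad <- setdiff(names(options), known)
  if (length(bad) > 0) {
    stop("unknown option(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- switch(subcommand,
    stats = .stage_stats(inputs, options),
    compare = .stage_compare(inputs, options),
    scenario = .stage_scenario(inputs, options),
    ancestral = .stage_ancestral(inputs, options),
    simulate = .stage_simulate(inputs, options, seed)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_reports(res, subcommand, out_dir, seed)
    return(invisible(res))
  }
  res
}

.load_order <- function(x) {
  if (inherits(x, "gene_order")) {
    return(x)
  }
  if (x %in% names(reference_orders())) {
    return(reference_orders(x))
  }
  if (!file.exists(x)) stop("no such gene-order file or registry name: ", x, call. = FALSE)
  read_gene_orders(x)[[1]]
}

.load_annotation <- function(x) {
  if (inherits(x, "annotation_table")) {
    return(x)
  }
  if (!file.exists(x)) stop("no such annotation file: ", x, call. = FALSE)
  first <- readLines(x, n = 1, warn = FALSE)
  if (startsWith(first, "LOCUS")) read_genbank(x) else read_annotation_tsv(x)
}

.stage_stats <- function(inputs, options) {
  table <- .load_annotation(inputs$annotation)
  out <- list(
    summary = summarize_genome(table),
    adjacencies = adjacency_records(table),
    strand_census = strand_census(table),
    size_discrepancies = validate_annotation(table)
  )
  if (!is.null(inputs$fasta)) {
    seqs <- read_fasta(inputs$fasta)
    out$composition <- composition(seqs[[1]])
    out$tandem_repeats <- find_tandem_repeats(
      seqs[[1]],
      min_unit = options$min_unit %||% 10,
      max_unit = options$max_unit %||% 60,
      min_copies = options$min_copies %||% 2,
      max_mismatch_fraction = options$max_mismatch_fraction %||% 0
    )
  }
  out
}

.stage_compare <- function(inputs, options) {
  a <- .load_order(inputs$a)
  b <- .load_order(inputs$b)
  cls <- classify_rearranged(a, b, rule = options$rule %||% "strand_or_adjacency")
  list(
    classification = cls,
    counts = rearrangement_counts(cls),
    breakpoint_distance = breakpoint_distance(a, b),
    shared_segments = shared_segments(
      list(a, b),
      min_len = options$min_len %||% 2
    )
  )
}

.stage_scenario <- function(inputs, options) {
  src <- .load_order(inputs$source)
  tgt <- .load_order(inputs$target)
  sc <- infer_scenario(src, tgt, anchor = options$anchor %||% "cob")
  list(
    scenario = sc,
    ops = tidy(sc),
    counts = glance(sc),
    narrative = scenario_narrative(sc)
  )
}

.stage_ancestral <- function(inputs, options) {
  ingroup <- lapply(inputs$ingroup, .load_order)
  names(ingroup) <- vapply(ingroup, order_name, character(1))
  outgroups <- lapply(inputs$outgroup, .load_order)
  names(outgroups) <- vapply(outgroups, order_name, character(1))
  call <- infer_ancestral(
    ingroup, outgroups,
    min_ingroup_support = options$min_ingroup_support %||% 2
  )
  list(call = call, segments = tidy(call), order = format_gene_order(call$order))
}

.stage_simulate <- function(inputs, options, seed) {
  cfg <- simulation_config(seed = seed, op_count = options$op_count %||% 1L)
  sim <- simulate_orders(cfg)
  genome <- simulate_genome(cfg)
  list(
    derived = format_gene_order(sim$derived),
    truth = tidy(sim$scenario),
    genome_table = genome$table,
    genome_seq = genome$seq
  )
}

.write_reports <- function(res, subcommand, out_dir, seed) {
  js <- list(subcommand = subcommand, seed = seed)
  for (nm in names(res)) {
    x <- res[[nm]]
    if (inherits(x, "scenario") || inherits(x, "ancestral_call")) next
    if (inherits(x, "data.frame")) {
      x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
      utils::write.table(
        as.data.frame(x),
        file.path(out_dir, paste0(subcommand, "_", nm, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      js[[nm]] <- x
    } else if (nm == "genome_seq") {
      write_fasta(
        stats::setNames(x, "simulated"),
        file.path(out_dir, "simulated_genome.fasta")
      )
    } else {
      js[[nm]] <- x
    }
  }
  jsonlite::write_json(
    js, file.path(out_dir, paste0(subcommand, "_report.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  log <- c(
    paste("package:", as.character(utils::packageVersion("mitorearr"))),
    paste("subcommand:", subcommand),
    paste("seed:", seed),
    paste(
      "config_hash:",
      sum(utf8ToInt(paste(subcommand, seed, collapse = " ")))
    )
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}
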