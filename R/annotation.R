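#' Read an annotation table from TSV
#'
#' Expected columns: `genome`, `gene`, `strand` (`+`/`-`), `start`, `end`,
#' and optionally `size` (the annotated feature size as printed; defaults to
#' `end - start + 1`) plus `start_codon`/`stop_codon`. Coordinates are
#' 1-based, fully closed.
#'
#' @param path Path to the TSV file.
#' @param genome_length Total genome length in bp; inferred as `max(end)`
#'   when missing.
#' @param circular Logical, default `TRUE`.
#' @return An `annotation_table`: a tibble of features sorted by start with
#'   attributes `genome_name`, `genome_length`, `circular`.
#' @export
#' @examples
#' tj <- read_annotation_tsv(mitorearr_example("tjaponicum_annotation.tsv"))
read_annotation_tsv <- function(path, genome_length = NULL, circular = TRUE) {
  raw <- utils::read.delim(
    path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = "character", blank.lines.skip = TRUE
  )
  need <- c("genome", "gene", "strand", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("annotation TSV lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  annotation_table(
    genome_name = raw$genome[1],
    gene = raw$gene,
    strand = ifelse(raw$strand %in% c("+", "1", "+1"), 1L, -1L),
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    size = if ("size" %in% names(raw)) {
      suppressWarnings(as.integer(raw$size))
    },
    start_codon = raw[["start_codon"]],
    stop_codon = raw[["stop_codon"]],
    genome_length = genome_length,
    circular = circular
  )
}

#' Construct an annotation table
#'
#' @param genome_name Genome identifier.
#' @param gene Gene tokens (canonical or aliases).
#' @param strand `+1`/`-1` (or `"+"`/`"-"`).
#' @param start,end 1-based closed coordinates.
#' @param size Annotated sizes; defaults to `end - start + 1`.
#' @param start_codon,stop_codon Optional codon annotations for PCGs.
#' @param genome_length Genome length in bp (default `max(end)`).
#' @param circular Logical.
#' @return An `annotation_table` tibble.
#' @export
annotation_table <- function(genome_name, gene, strand, start, end,
                             size = NULL, start_codon = NULL,
                             stop_codon = NULL, genome_length = NULL,
                             circular = TRUE) {
  if (length(gene) == 0) {
    stop("empty annotation table", call. = FALSE)
  }
  gene <- canonical_gene(gene)
  if (is.character(strand)) strand <- ifelse(strand == "+", 1L, -1L)
  strand <- as.integer(strand)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end) || any(start < 1)) {
    stop("invalid coordinates: start must be >= 1 and numeric", call. = FALSE)
  }
  if (any(end < start)) {
    stop(
      "feature(s) with end < start (wrapping the origin is not supported): ",
      paste(gene[end < start], collapse = ", "),
      call. = FALSE
    )
  }
  dup <- gene[duplicated(gene)]
  if (length(dup) > 0) {
    stop("duplicated gene(s) in annotation: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  span <- end - start + 1L
  size <- if (is.null(size)) span else ifelse(is.na(size), span, as.integer(size))
  out <- tibble::tibble(
    gene = gene,
    class = gene_class(gene),
    strand = strand,
    start = start,
    end = end,
    size = size,
    span = span
  )
  if (!is.null(start_codon)) out$start_codon <- dplyr::na_if(start_codon, "")
  if (!is.null(stop_codon)) out$stop_codon <- dplyr::na_if(stop_codon, "")
  out <- dplyr::arrange(out, .data$start)
  genome_length <- as.integer(genome_length %||% max(out$end))
  if (any(out$end > genome_length)) {
    stop("feature(s) extend past genome_length: ",
      paste(out$gene[out$end > genome_length], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    out,
    genome_name = genome_name,
    genome_length = genome_length,
    circular = isTRUE(circular),
    class = c("annotation_table", class(out))
  )
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(
    "<annotation_table '", attr(x, "genome_name"), "': ",
    nrow(x), " features, ", attr(x, "genome_length"), " bp, ",
    if (attr(x, "circular")) "circular" else "linear", ">\n",
    sep = ""
  )
  NextMethod()
}

#' Validate an annotation table
#'
#' Checks the printed size column against the positional span
#' (`end - start + 1`). Positions are authoritative for all positional
#' computations; conflicting size cells are reported here.
#'
#' @param table An `annotation_table`.
#' @return A tibble of discrepancies (zero rows when consistent).
#' @export
validate_annotation <- function(table) {
  bad <- dplyr::filter(table, .data$size != .data$span)
  tibble::tibble(
    gene = bad$gene,
    annotated_size = bad$size,
    positional_span = bad$span,
    note = "size column conflicts with positions; positions take precedence"
  )
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata/`; when missing, lists
#'   the available files.
#' @return A file path (or a character vector of file names).
#' @export
mitorearr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mitorearr")))
  }
  path <- system.file("extdata", file, package = "mitorearr")
  if (!nzchar(path)) stop("no packaged file named ", file, call. = FALSE)
  path
}

#' Read a GenBank flat file into an annotation table
#'
#' A minimal reader for the feature keys `gene`, `CDS`, `tRNA`, `rRNA` and
#' `D-loop`. Gene symbols are taken from `/gene=` (or `/product=`)
#' qualifiers; `complement(a..b)` marks the minority strand. CDS/tRNA/rRNA
#' features take precedence over plain `gene` features for the same symbol.
#'
#' @param path Path to a GenBank flat file.
#' @param circular Logical, default `TRUE`.
#' @return An `annotation_table`.
#' @export
read_genbank <- function(path, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  genome_name <- if (length(locus) > 0) strsplit(trimws(locus[1]), "[[:space:]]+")[[1]][2] else ""
  glen <- if (length(locus) > 0) {
    m <- regmatches(locus[1], regexpr("[0-9]+(?= bp)", locus[1], perl = TRUE))
    if (length(m) > 0) as.integer(m) else NULL
  }
  f_start <- grep("^FEATURES", lines)
  f_end <- grep("^(ORIGIN|//)", lines)
  f_end <- if (length(f_end) > 0) min(f_end[f_end > f_start[1]]) else length(lines) + 1L
  if (length(f_start) == 0) stop("no FEATURES block in ", path, call. = FALSE)
  block <- lines[(f_start[1] + 1):(f_end - 1)]

  keys <- c("gene", "CDS", "tRNA", "rRNA", "D-loop")
  is_feat <- grepl("^ {5}\\S", block)
  idx <- which(is_feat)
  feats <- list()
  for (i in seq_along(idx)) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1] - 1L else length(block)
    head_parts <- strsplit(trimws(block[from]), "[[:space:]]+")[[1]]
    key <- head_parts[1]
    if (!key %in% keys) next
    loc <- paste(head_parts[-1], collapse = "")
    qual <- block[(from + 1):to]
    strand <- if (grepl("complement", loc)) -1L else 1L
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2) next
    gene_q <- grep("/gene=", qual, value = TRUE)
    prod_q <- grep("/product=", qual, value = TRUE)
    sym <- if (length(gene_q) > 0) {
      gsub('.*/gene="?([^"]+)"?.*', "\\1", gene_q[1])
    } else if (key == "D-loop") {
      "CR"
    } else if (length(prod_q) > 0) {
      gsub('.*/product="?([^"]+)"?.*', "\\1", prod_q[1])
    } else {
      next
    }
    feats[[length(feats) + 1]] <- list(
      key = key, gene = sym, strand = strand,
      start = min(nums), end = max(nums)
    )
  }
  if (length(feats) == 0) stop("no usable features in ", path, call. = FALSE)
  df <- dplyr::bind_rows(lapply(feats, tibble::as_tibble))
  df$gene <- canonical_gene(df$gene)
  # prefer typed features over bare 'gene' records of the same symbol
  df$rank <- ifelse(df$key == "gene", 2L, 1L)
  df <- dplyr::slice_min(
    dplyr::group_by(df, .data$gene), .data$rank,
    n = 1, with_ties = FALSE
  )
  df <- dplyr::ungroup(df)
  annotation_table(
    genome_name = genome_name,
    gene = df$gene, strand = df$strand,
    start = df$start, end = df$end,
    genome_length = glen, circular = circular
  )
}
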