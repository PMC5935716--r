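#' Canonical mitochondrial gene vocabulary
#'
#' The 37 genes of a typical animal mitochondrial genome plus the control
#' region marker: 13 protein-coding genes, 22 tRNA genes (with the two
#' leucine and two serine isoacceptors disambiguated as `trnL1`/`trnL2` and
#' `trnS1`/`trnS2`), two rRNA genes, and `CR`.
#'
#' @return A tibble with columns `gene` (canonical token) and `class`
#'   (`"PCG"`, `"tRNA"`, `"rRNA"` or `"CR"`).
#' @export
#' @examples
#' gene_vocabulary()
gene_vocabulary <- function() {
  pcg <- c(
    "atp6", "atp8", "cob", "cox1", "cox2", "cox3",
    "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6"
  )
  trna <- paste0("trn", c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K",
    "L1", "L2", "M", "N", "P", "Q", "R", "S1", "S2",
    "T", "V", "W", "Y"
  ))
  tibble::tibble(
    gene = c(pcg, trna, "rrnS", "rrnL", "CR"),
    class = c(
      rep("PCG", length(pcg)),
      rep("tRNA", length(trna)),
      "rRNA", "rRNA", "CR"
    )
  )
}

# Lookup environment built once at load time.
.vocab <- new.env(parent = emptyenv())

.vocab_table <- function() {
  if (is.null(.vocab$table)) {
    .vocab$table <- gene_vocabulary()
    .vocab$class <- stats::setNames(.vocab$table$class, .vocab$table$gene)
    .vocab$alias <- .build_alias_map()
  }
  .vocab$table
}

# One-letter tRNA symbols (Fig-2 style labels) and common spelling variants
# map bijectively onto canonical tokens.
.build_alias_map <- function() {
  vocab <- gene_vocabulary()
  trna <- vocab$gene[vocab$class == "tRNA"]
  short <- sub("^trn", "", trna)
  alias <- stats::setNames(trna, short)
  # case variants of canonical tokens
  canon <- stats::setNames(vocab$gene, tolower(vocab$gene))
  # frequent alternative spellings
  extra <- c(
    "nad4L" = "nad4l", "cytb" = "cob", "cob" = "cob",
    "rrns" = "rrnS", "rrnl" = "rrnL", "srRNA" = "rrnS", "lrRNA" = "rrnL",
    "d-loop" = "CR", "D-loop" = "CR", "control_region" = "CR"
  )
  c(alias, canon, extra)
}

#' Resolve gene tokens to canonical form
#'
#' Accepts canonical tokens, one-letter tRNA symbols (`"W"`, `"L1"`, ...),
#' and common spelling variants (`nad4L`, `D-loop`).
#'
#' @param tokens Character vector of gene tokens (no orientation prefix).
#' @return Character vector of canonical tokens.
#' @export
canonical_gene <- function(tokens) {
  .vocab_table()
  out <- character(length(tokens))
  vocab <- .vocab$table$gene
  hit <- tokens %in% vocab
  out[hit] <- tokens[hit]
  rest <- !hit
  if (any(rest)) {
    mapped <- .vocab$alias[tokens[rest]]
    bad <- is.na(mapped)
    if (any(bad)) {
      stop(
        "unknown gene token(s): ",
        paste(unique(tokens[rest][bad]), collapse = ", "),
        call. = FALSE
      )
    }
    out[rest] <- unname(mapped)
  }
  out
}

#' Gene class lookup
#'
#' @param genes Character vector of canonical gene tokens.
#' @return Character vector of classes (`"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"`).
#' @export
gene_class <- function(genes) {
  .vocab_table()
  cls <- .vocab$class[genes]
  if (anyNA(cls)) {
    stop(
      "unknown gene token(s): ",
      paste(unique(genes[is.na(cls)]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(cls)
}

# Short display label: one-letter tRNA symbol, otherwise the token itself.
.short_label <- function(genes) {
  cls <- gene_class(genes)
  ifelse(cls == "tRNA", sub("^trn", "", genes), genes)
}
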