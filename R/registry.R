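#' Packaged reference gene orders
#'
#' Immutable reference arrangements used throughout the package:
#'
#' * `PanGO` — the ancestral (pancrustacean ground-pattern) insect
#'   mitochondrial gene order.
#' * `ant1GO` — the plesiomorphic hymenopteran gene order used as outgroup
#'   ground pattern; its cluster patterns match PanGO (figure-transcribed).
#' * `ChalcidoidGO` — the presumed ancestral gene order of Chalcidoidea:
#'   ant1GO backbone with the ten-gene inverted block
#'   `-nad3 -trnG -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1`.
#' * `TrichogrammaGO` — the derived *Trichogramma* gene order, transcribed
#'   from the printed annotation table (authoritative).
#' * `Megaphragma`, `Philotrypesis`, `Ceratosolen`, `Nasonia_vitripennis`,
#'   `Nasonia_giraulti` — other chalcidoid arrangements, best-effort
#'   figure transcriptions (`metadata$confidence == "figure"`).
#'
#' @param name Optional single name; when omitted the full named list is
#'   returned.
#' @return A [gene_order()] or a named list of them.
#' @export
#' @examples
#' reference_orders("TrichogrammaGO")
reference_orders <- function(name = NULL) {
  reg <- .registry()
  if (is.null(name)) {
    return(reg)
  }
  if (!name %in% names(reg)) {
    stop(
      "unknown reference order: ", name, "; available: ",
      paste(names(reg), collapse = ", "),
      call. = FALSE
    )
  }
  reg[[name]]
}

.registry_cache <- new.env(parent = emptyenv())

.registry <- function() {
  if (!is.null(.registry_cache$reg)) {
    return(.registry_cache$reg)
  }
  pan <- paste(
    "trnI -trnQ trnM nad2 trnW -trnC -trnY",
    "cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3",
    "trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l",
    "trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR"
  )
  chal <- paste(
    "trnI -trnQ trnM nad2 trnW -trnC -trnY",
    "-nad3 -trnG -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1",
    "trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l",
    "trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR"
  )
  tricho <- paste(
    "-trnW -nad2 -trnQ -trnY -cox1 trnE -trnF -trnI -trnS1 -trnN -trnC",
    "-cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2",
    "-nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob trnS2 -nad1 -trnL1",
    "-rrnL -trnA -trnG -rrnS -trnV -trnR -nad3 -trnM CR"
  )
  mega <- paste(
    "trnM trnI -trnQ nad2 -trnC trnW -trnY",
    "-cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 -nad3 -trnG",
    "trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l",
    "trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR"
  )
  philo <- paste(
    "trnI trnM -trnQ nad2 trnW -trnY -trnC",
    "-cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 trnS1 trnG nad3",
    "trnA trnR trnN trnE -trnF -nad5 -trnH -nad4 -nad4l",
    "trnT -trnP nad6 cob -nad1 trnS2 -trnL1 -rrnL -trnV -rrnS CR"
  )
  cerato <- paste(
    "trnM trnI -trnQ nad2 -trnY trnW -trnC",
    "-cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 nad3 trnG",
    "trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l",
    "trnT -trnP nad6 cob -nad1 trnS2 -trnL1 -rrnL -trnV -rrnS CR"
  )
  nasonia <- paste(
    "trnI -trnQ trnM nad2 trnW -trnC -trnY",
    "-nad3 -trnG -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1",
    "trnA trnR trnN trnS1 trnE -trnF -nad5 trnT -trnH -nad4 -nad4l",
    "-trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR"
  )
  mk <- function(text, nm, confidence) {
    out <- parse_gene_order(text, name = nm)
    attr(out, "metadata") <- list(confidence = confidence)
    out
  }
  reg <- list(
    PanGO = mk(pan, "PanGO", "literature"),
    ant1GO = mk(pan, "ant1GO", "figure"),
    ChalcidoidGO = mk(chal, "ChalcidoidGO", "figure"),
    TrichogrammaGO = mk(tricho, "TrichogrammaGO", "table"),
    Megaphragma = mk(mega, "Megaphragma", "figure"),
    Philotrypesis = mk(philo, "Philotrypesis", "figure"),
    Ceratosolen = mk(cerato, "Ceratosolen", "figure"),
    Nasonia_vitripennis = mk(nasonia, "Nasonia_vitripennis", "figure"),
    Nasonia_giraulti = mk(nasonia, "Nasonia_giraulti", "figure")
  )
  .registry_cache$reg <- reg
  reg
}
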