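Package: mitorearr
Title: Comparative Analysis of Mitochondrial Gene Orders and Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitochondrial genome analysis built around
    signed circular gene orders. Computes annotation-table statistics
    (intergenic and overlapping nucleotides, strand usage, coding fractions),
    nucleotide-composition and codon-usage summaries (AT/GC skew, RSCU),
    control-region motif and tandem-repeat scans, rearranged-gene
    classification against ancestral arrangements, conserved-segment
    detection, rule-based ancestral gene-order assembly, and reconstruction
    of rearrangement scenarios (inversions, transpositions, inverse
    transpositions, and tandem-duplication-random-loss events) from the
    strong interval tree of the common intervals between two gene orders.
    Includes a seeded simulator for gene orders with known rearrangement
    histories and annotated genome sequences with controlled composition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
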