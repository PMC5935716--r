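test_that("composition and skews follow the strand-asymmetry formulas", {
  expect_equal(composition("AATT")$at_skew, 0)
  expect_equal(composition("AAAT")$at_skew, 0.5) # (3-1)/(3+1)
  expect_equal(composition("GGGC")$gc_skew, 0.5)
  x <- composition("AAATTGC")
  expect_equal(x$at_content, round(100 * 5 / 7, 2))

  # ambiguity codes excluded; degenerate denominators give NA, not errors
  expect_equal(composition("AANNT")$length, 3L)
  expect_true(is.na(composition("GGCC")$at_skew))
  expect_true(is.na(composition("")$at_skew))

  # reverse complement negates both skews
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
      prob = c(.4, .1, .15, .35)
    ), collapse = "")
    f <- composition(s)
    r <- composition(revcomp(s))
    expect_equal(r$at_skew, -f$at_skew)
    expect_equal(r$gc_skew, -f$gc_skew)
    expect_true(abs(f$at_skew) <= 1 && abs(f$gc_skew) <= 1)
    expect_true(f$at_content >= 0 && f$at_content <= 100)
  }
})

test_that("RSCU follows count * family_size / family_total with stop codons excluded", {
  # equal counts within a family -> RSCU 1.0 (Phe family: TTT/TTC)
  cu <- codon_usage(c(x = "TTTTTC"))
  phe <- cu[cu$aa == "F", ]
  expect_equal(phe$rscu, c(1, 1))

  # two-codon family with counts {3, 1} -> RSCU {1.5, 0.5}
  cu2 <- codon_usage(c(x = "TTTTTTTTTTTC"))
  phe2 <- cu2[cu2$aa == "F", ]
  expect_equal(phe2$rscu[phe2$codon == "TTT"], 1.5)
  expect_equal(phe2$rscu[phe2$codon == "TTC"], 0.5)

  # unobserved families report NA, stop codons never get RSCU
  expect_true(all(is.na(cu$rscu[cu$aa == "*"])))
  expect_true(all(is.na(cu$rscu[cu$aa == "G"])))

  # family-sum conservation on random coding sequences
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 3 * 120, replace = TRUE), collapse = "")
    cu <- codon_usage(list(s))
    sums <- stats::aggregate(rscu ~ aa, data = cu[cu$aa != "*", ], FUN = sum)
    fam <- stats::aggregate(codon ~ aa, data = cu[cu$aa != "*", ], FUN = length)
    got <- merge(sums, fam)
    observed <- got[!is.na(got$rscu), ]
    expect_equal(observed$rscu, as.numeric(observed$codon), tolerance = 1e-12)
  }

  # truncated terminal stops are tolerated, other frame violations are not
  expect_silent(codon_usage(c(ok = "ATGAAATA")))
  expect_error(codon_usage(c(bad = "ATGAAAG")), "bad")
})

test_that("RSCU agrees with the seqinr implementation on a shared input", {
  skip_if_not_installed("seqinr")
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 3 * 200, replace = TRUE), collapse = "")
  ours <- codon_usage(list(s))
  ref <- seqinr::uco(strsplit(tolower(s), "")[[1]], index = "rscu")
  # seqinr computes RSCU under the standard code; compare families whose
  # composition is identical in the standard and invertebrate mito codes
  code <- Biostrings::getGeneticCode("SGC4")
  std <- Biostrings::GENETIC_CODE
  shared <- names(code)[code == std[names(code)] &
    code %in% c("F", "D", "E", "H", "Q", "N", "K", "C", "Y")]
  for (cod in shared) {
    expect_equal(
      ours$rscu[ours$codon == cod],
      unname(ref[tolower(cod)]),
      tolerance = 1e-8
    )
  }
})

test_that("terminal codons are extracted strand-aware with truncated stops", {
  # synthetic two-gene genome: plus-strand complete stop, minus-strand gene,
  # and a 3k+1 gene ending in a truncated T
  g1 <- "ATGAAATTTTAA" # 12 nt, ATG..TAA
  g2core <- "ATGCCCGGGTAA"
  g2 <- revcomp(g2core) # minority strand
  g3 <- "ATGAAAAAAT" # 10 nt = 3k+1, truncated stop T
  seq <- paste0(g1, "AC", g2, g3, "GATTACA")
  tab <- annotation_table(
    "syn",
    gene = c("cox1", "cox2", "cox3"),
    strand = c(1L, -1L, 1L),
    start = c(1, 15, 27),
    end = c(12, 26, 36),
    genome_length = nchar(seq)
  )
  tc <- extract_terminal_codons(tab, seq)
  expect_equal(tc$start_codon[tc$gene == "cox1"], "ATG")
  expect_equal(tc$stop_codon[tc$gene == "cox1"], "TAA")
  expect_false(tc$stop_truncated[tc$gene == "cox1"])
  # minority-strand gene read from the reverse complement
  expect_equal(tc$start_codon[tc$gene == "cox2"], "ATG")
  expect_equal(tc$stop_codon[tc$gene == "cox2"], "TAA")
  expect_equal(tc$stop_codon[tc$gene == "cox3"], "T")
  expect_true(tc$stop_truncated[tc$gene == "cox3"])

  short <- annotation_table("syn", "atp8", 1L, 1, 4, genome_length = nchar(seq))
  expect_error(extract_terminal_codons(short, seq), "shorter")
})

test_that("tandem repeats are recovered with unit length and copy number", {
  unit21 <- "AGCCTCAAAAATCGGGGTTTT"
  hit <- find_tandem_repeats(strrep(unit21, 3), min_unit = 10)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$unit_length, 21L)
  expect_equal(hit$copies, 3)
  expect_equal(hit$unit, unit21)

  ta <- find_tandem_repeats(strrep("TA", 40), min_unit = 1)
  expect_equal(nrow(ta), 1)
  expect_equal(ta$unit_length, 2L)
  expect_equal(ta$copies, 40)

  set.seed(13)
  noise <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  none <- find_tandem_repeats(noise, min_unit = 15, max_unit = 40, min_copies = 3)
  expect_equal(nrow(none), 0)

  # mismatch bridging: one mutated base inside three copies
  mut <- strrep(unit21, 3)
  substr(mut, 30, 30) <- "G" # reference base at 30 is A
  perfect <- find_tandem_repeats(mut, min_unit = 10, max_mismatch_fraction = 0)
  tolerant <- find_tandem_repeats(mut, min_unit = 10, max_mismatch_fraction = 0.05)
  expect_true(nrow(tolerant) >= 1)
  expect_equal(max(tolerant$copies[tolerant$unit_length == 21]), 3)
  expect_true(all(perfect$copies < 3))
})

test_that("control-region elements are detected in a constructed positive control", {
  arm <- "GCATTGCAG"
  hairpin <- paste0(arm, "TTAATT", revcomp(arm))
  seqcr <- paste0(
    strrep("T", 8), "CC", strrep("TAA", 4), "CC", hairpin, "CC",
    "TATA", "CC", "GAAAT", "CC", "GAGAAAGAAG"
  )
  el <- scan_control_region(seqcr)
  expect_true(all(c("polyT", "TA(A)n", "stem-loop", "TATA", "G(A)nT", "GA-rich")
  %in% el$element))
  expect_true(all(el$start >= 1 & el$end <= nchar(seqcr)))

  none <- scan_control_region(strrep("C", 120))
  expect_equal(nrow(none), 0)

  # stem arms with one mismatch still fold at tolerance 1
  arm2 <- revcomp(arm)
  substr(arm2, 4, 4) <- "A"
  hp_mm <- paste0("CCCC", arm, "TTTAAA", arm2, "CCCC")
  sl <- find_stem_loop(hp_mm, stem_range = c(5, 12), loop_range = c(3, 10),
                       max_mismatch = 1)
  expect_false(is.null(sl))
  expect_equal(sl$mismatches, 1)
  expect_null(find_stem_loop(hp_mm, stem_range = c(9, 12), loop_range = c(3, 10),
                             max_mismatch = 0))
})
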