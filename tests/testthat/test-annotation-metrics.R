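test_that("adjacency records reproduce the printed overlaps and spacers", {
  tj <- tj_table()
  adj <- adjacency_records(tj)
  expect_equal(nrow(adj), nrow(tj)) # circular: n features, n adjacencies

  ovl <- adj[adj$relation == "overlap", ]
  expect_setequal(
    paste(ovl$upstream, ovl$downstream, sep = "-"),
    c("atp6-atp8", "nad4-nad4l", "trnT-trnP", "trnS2-nad1", "trnV-trnR")
  )
  expect_equal(ovl$length[ovl$upstream == "atp6"], 7)
  expect_equal(ovl$length[ovl$upstream == "trnT"], 1)

  to <- to_table()
  ovl2 <- adjacency_records(to)
  ovl2 <- ovl2[ovl2$relation == "overlap", ]
  expect_setequal(
    paste(ovl2$upstream, ovl2$downstream, sep = "-"),
    c("atp6-atp8", "nad4-nad4l", "trnT-trnP", "trnS2-nad1", "trnV-trnR")
  )
  expect_equal(sum(ovl2$length), 18)

  abut <- annotation_table("x", c("cox1", "cox2"), 1L, c(1, 11), c(10, 20))
  rec <- adjacency_records(abut)
  expect_equal(rec$relation[1], "abut")
  expect_equal(rec$length[1], 0)
})

test_that("adjacency gap multiset is invariant under coordinate rotation", {
  tj <- tj_table()
  glen <- attr(tj, "genome_length")
  base <- adjacency_records(tj)
  signed_gap <- function(adj) {
    sort(ifelse(adj$relation == "overlap", -adj$length, adj$length))
  }
  # cut the circle inside known intergenic spacers so no feature wraps
  for (cut in c(5060L, 1150L, 3120L)) {
    s2 <- ((tj$start - cut) %% glen) + 1L
    e2 <- ((tj$end - cut) %% glen) + 1L
    expect_true(all(e2 >= s2))
    rot <- annotation_table(
      "rot", tj$gene, tj$strand, s2, e2,
      genome_length = glen
    )
    expect_equal(signed_gap(adjacency_records(rot)), signed_gap(base))
  }
})

test_that("genome summaries match the printed structure statistics", {
  s <- summarize_genome(tj_table())
  expect_equal(s$genome_length, 15962L)
  expect_equal(s$total_intergenic, 547L)
  expect_equal(s$longest_spacer, 81L)
  expect_equal(s$longest_spacer_between, "atp8-trnD")
  expect_equal(s$total_overlap, 19L)
  expect_equal(s$overlap_location_count, 5L)
  expect_equal(s$pcg_total_length, 11202L)
  expect_equal(s$pcg_fraction, 70.18)
  expect_equal(s$cr_length, 593L)
  expect_equal(s$trna_min_size, 59L) # trnS1
  expect_equal(s$trna_max_size, 70L) # trnK
  # positive-gap location count derived from positions (the printed "17
  # locations" is not reproducible from the printed coordinates)
  expect_equal(s$intergenic_location_count, 22L)

  s2 <- summarize_genome(to_table())
  expect_equal(s2$genome_length, 16472L)
  expect_equal(s2$total_overlap, 18L)
  expect_equal(s2$overlap_location_count, 5L)
  expect_equal(s2$longest_spacer, 171L)
  expect_equal(s2$longest_spacer_between, "trnF-trnI")
  expect_equal(s2$intergenic_location_count, 19L)
  expect_equal(s2$pcg_total_length, 11190L)
  expect_equal(s2$pcg_fraction, 67.93)
  expect_equal(s2$cr_length, 830L)

  whole <- annotation_table("x", "rrnL", 1L, 1, 5000)
  sw <- summarize_genome(whole)
  expect_equal(sw$total_intergenic, 0L)
  expect_equal(sw$total_overlap, 0L)

  expect_error(adjacency_records(annotation_table("x", character(0), integer(0), integer(0), integer(0))), "empty|invalid")
})

test_that("strand census matches the printed per-class counts", {
  cen <- strand_census(tj_table())
  expect_equal(cen$minority[cen$class == "tRNA"], 18L)
  expect_equal(cen$majority[cen$class == "tRNA"], 4L)
  expect_equal(cen$minority[cen$class == "PCG"], 11L)
  expect_equal(cen$majority[cen$class == "PCG"], 2L)
  tj <- tj_table()
  maj_pcg <- tj$gene[tj$class == "PCG" & tj$strand == 1L]
  expect_setequal(maj_pcg, c("nad6", "cob"))

  one_strand <- annotation_table("x", c("cox1", "trnW"), -1L, c(1, 2000), c(1500, 2065))
  cen2 <- strand_census(one_strand)
  expect_true(all(cen2$majority == 0L))
})

test_that("size column discrepancies are reported with positions taking precedence", {
  v <- validate_annotation(tj_table())
  expect_equal(v$gene, "nad2")
  expect_equal(v$annotated_size, 1014L)
  expect_equal(v$positional_span, 1012L)
  v2 <- validate_annotation(to_table())
  expect_equal(v2$gene, "nad2")
})

test_that("coverage identity holds on the fixtures and simulated genomes", {
  expect_true(coverage_identity(tj_table()))
  expect_true(coverage_identity(to_table()))
  for (seed in 1:100) {
    set.seed(seed)
    gaps <- sample(-3:40, 6)
    names(gaps) <- sample(setdiff(gene_vocabulary()$gene, "CR"), 6)
    sim <- simulate_genome(
      simulation_config(seed = seed, genome_length = 16000L),
      gaps = gaps
    )
    expect_true(coverage_identity(sim$table))
  }
})

test_that("features wrapping the origin are rejected explicitly", {
  expect_error(
    annotation_table("x", "cox1", 1L, 15900, 30),
    "wrapping"
  )
})
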