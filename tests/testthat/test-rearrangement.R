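test_that("extremity adjacencies count and encode gene neighborhoods", {
  pan <- reference_orders("PanGO")
  expect_length(adjacency_set(pan), 37) # CR excluded by default
  expect_length(adjacency_set(pan, include_cr = TRUE), 38)

  two <- parse_gene_order("cox1 cox2")
  expect_setequal(
    adjacency_set(two),
    c("cox1.h|cox2.t", "cox1.t|cox2.h")
  )

  # rotation leaves the adjacency set untouched
  set.seed(21)
  for (i in 1:10) {
    x <- random_order(9)
    rot <- linearize(x, sample(x$gene, 1))
    expect_setequal(adjacency_set(rot), adjacency_set(x))
  }
})

test_that("rearranged-gene classification reproduces the published counts", {
  tricho <- reference_orders("TrichogrammaGO")
  pan <- reference_orders("PanGO")
  cl <- classify_rearranged(tricho, pan)
  counts <- rearrangement_counts(cl)
  expect_equal(counts$rearranged[counts$class == "tRNA"], 15L)
  expect_equal(counts$total[counts$class == "tRNA"], 22L)
  expect_equal(counts$rearranged[counts$class == "PCG"], 7L)
  expect_equal(counts$total[counts$class == "PCG"], 13L)
  expect_setequal(
    cl$gene[cl$class == "tRNA" & cl$status == "unrearranged"],
    c("trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1")
  )
  # nad2 keeps a neighbourhood but switches strand: rearranged by the rule
  expect_equal(cl$status[cl$gene == "nad2"], "rearranged")
  expect_true(cl$strand_changed[cl$gene == "nad2"])
  expect_gte(cl$adjacencies_preserved[cl$gene == "nad2"], 1L)

  # identity comparison: nothing rearranged
  self <- classify_rearranged(pan, pan)
  expect_true(all(self$status == "unrearranged"))

  # orientation-blind rule keeps nad2 unrearranged
  blind <- classify_rearranged(tricho, pan, rule = "position_only")
  expect_equal(blind$status[blind$gene == "nad2"], "unrearranged")

  expect_error(
    classify_rearranged(parse_gene_order("cox1 cox2"), parse_gene_order("cox1 cox3")),
    "gene sets"
  )
})

test_that("every single-gene inversion flags exactly that gene", {
  base <- random_order(10, seed = 31)
  for (k in seq_len(nrow(base))) {
    derived <- base
    derived$orientation[k] <- -derived$orientation[k]
    derived <- gene_order(derived$gene, derived$orientation)
    cl <- classify_rearranged(derived, base)
    expect_equal(cl$gene[cl$status == "rearranged"], base$gene[k])
  }
})

test_that("classification and distance are rotation-invariant", {
  set.seed(41)
  tricho <- reference_orders("TrichogrammaGO")
  pan <- reference_orders("PanGO")
  d0 <- breakpoint_distance(tricho, pan)
  cl0 <- classify_rearranged(tricho, pan)
  for (i in 1:5) {
    t2 <- linearize(tricho, sample(tricho$gene, 1))
    p2 <- linearize(pan, sample(pan$gene, 1))
    expect_equal(breakpoint_distance(t2, p2), d0)
    cl2 <- classify_rearranged(t2, p2)
    m <- merge(as.data.frame(cl0), as.data.frame(cl2), by = "gene")
    expect_true(all(m$status.x == m$status.y))
  }
})

test_that("breakpoint distance matches the brute-force oracle and its axioms", {
  tricho <- reference_orders("TrichogrammaGO")
  pan <- reference_orders("PanGO")
  chal <- reference_orders("ChalcidoidGO")
  expect_equal(
    breakpoint_distance(pan, tricho),
    oracle_breakpoint(pan, tricho)
  )
  expect_equal(
    breakpoint_distance(chal, tricho),
    oracle_breakpoint(chal, tricho)
  )
  expect_equal(breakpoint_distance(pan, pan), 0L)

  # one internal block inversion breaks exactly two adjacencies
  base <- reference_orders("PanGO")
  lin <- drop_cr(base)
  idx <- 5:9
  genes <- lin$gene
  ori <- lin$orientation
  genes[idx] <- rev(genes[idx])
  ori[idx] <- -rev(ori[idx])
  inv <- gene_order(genes, ori)
  expect_equal(breakpoint_distance(base, inv), 2L)

  # symmetry and empirical triangle inequality on random orders
  set.seed(51)
  for (i in 1:10) {
    x <- random_order(12, seed = i)
    y <- gene_order(sample(x$gene), sample(c(-1L, 1L), 12, replace = TRUE))
    z <- gene_order(sample(x$gene), sample(c(-1L, 1L), 12, replace = TRUE))
    expect_equal(breakpoint_distance(x, y), breakpoint_distance(y, x))
    expect_equal(breakpoint_distance(x, y), oracle_breakpoint(x, y))
    expect_lte(
      breakpoint_distance(x, z),
      breakpoint_distance(x, y) + breakpoint_distance(y, z)
    )
  }
})

test_that("shared segments recover the published conserved blocks", {
  reg <- reference_orders()
  segs <- shared_segments(reg[c(
    "PanGO", "ant1GO", "Megaphragma", "Philotrypesis", "Ceratosolen"
  )])
  expect_true(
    "trnE -trnF -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob" %in% segs$segment
  )

  segs2 <- shared_segments(reg[c(
    "ant1GO", "PanGO", "TrichogrammaGO", "Megaphragma"
  )])
  expect_true(any(grepl("trnS2 -nad1 -trnL1 -rrnL", segs2$segment, fixed = TRUE)))

  # two identical orders share the whole genome as one segment
  whole <- shared_segments(list(reg$PanGO, reg$PanGO))
  expect_equal(nrow(whole), 1)
  expect_equal(whole$length, 37)

  # chalcidoid "-D k" quirk: conserved across all packaged chalcidoids
  chalc <- reg[c(
    "TrichogrammaGO", "Megaphragma", "Philotrypesis", "Ceratosolen",
    "Nasonia_vitripennis"
  )]
  segs3 <- shared_segments(chalc)
  expect_true(any(grepl("-trnD trnK", segs3$segment, fixed = TRUE)))
})

test_that("reported segments are maximal: one-gene extensions break conservation", {
  reg <- reference_orders()
  input <- reg[c("PanGO", "ant1GO", "Megaphragma", "Philotrypesis", "Ceratosolen")]
  segs <- shared_segments(input)
  ref <- drop_cr(input[[1]])
  n <- nrow(ref)
  for (r in seq_len(nrow(segs))) {
    g <- segs$genes[[r]]
    if (nrow(g) >= n) next
    first <- match(g$gene[1], ref$gene)
    last <- match(g$gene[nrow(g)], ref$gene)
    left <- ((first - 2L) %% n) + 1L
    right <- (last %% n) + 1L
    ext_left <- dplyr::bind_rows(ref[left, c("gene", "orientation")], g)
    ext_right <- dplyr::bind_rows(g, ref[right, c("gene", "orientation")])
    expect_false(all(vapply(input, carries_segment, logical(1), segment = ext_left)))
    expect_false(all(vapply(input, carries_segment, logical(1), segment = ext_right)))
  }
})

test_that("whole-segment inversions count as carrying, configurably", {
  x <- parse_gene_order("cox1 cox2 -cox3 nad1 nad2")
  seg <- parse_gene_order("cox3 -cox2")
  expect_true(carries_segment(x, seg, allow_flip = TRUE))
  expect_false(carries_segment(x, seg, allow_flip = FALSE))
  expect_error(
    shared_segments(list(parse_gene_order("cox1 cox2"), parse_gene_order("nad1 nad2"))),
    "gene sets"
  )
})

test_that("PHYLIP distance export is square and symmetric", {
  reg <- reference_orders()
  tmp <- tempfile(fileext = ".dist")
  d <- write_phylip_distances(
    reg[c("PanGO", "ChalcidoidGO", "TrichogrammaGO")], tmp
  )
  lines <- readLines(tmp)
  expect_equal(trimws(lines[1]), "3")
  expect_length(lines, 4)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})
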