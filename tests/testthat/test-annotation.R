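test_that("probe center is the left middle base", {
  expect_equal(probe_center(100L, 150L), 124L)
  expect_equal(probe_center(1000L, 1001L), 1000L)
  expect_equal(probe_center(0L, 50L), 24L)
  expect_equal(probe_center(0L, 51L), 25L)  # odd width: exact middle
})

test_that("promoter window is strand-aware, inclusive, and clips/wraps", {
  w <- promoter_window(10000L, "+")
  expect_equal(c(w$lo, w$hi), c(9500L, 10100L))
  w <- promoter_window(10000L, "-")
  expect_equal(c(w$lo, w$hi), c(9900L, 10500L))
  # linear clip at the left edge
  w <- promoter_window(200L, "+", genome_length = 50000L, circular = FALSE)
  expect_equal(c(w$lo, w$hi), c(0L, 300L))
  # circular wrap across the origin
  w <- promoter_window(100L, "+", genome_length = 10000L, circular = TRUE)
  expect_true(w$wraps)
  expect_equal(c(w$lo, w$hi), c(9600L, 200L))
  expect_true(chipocc:::window_contains(w, 9700L))
  expect_true(chipocc:::window_contains(w, 50L))
  expect_false(chipocc:::window_contains(w, 5000L))
})

test_that("a probe annotates to a gene iff its center is in the window", {
  genes <- gene_table("gX", 10000L, 11000L, "+")
  g <- genome_model("chr", 50000L, circular = FALSE, genes = genes)
  probes <- tibble::tibble(start = c(9500L, 9474L), end = c(9550L, 9524L))
  ann <- annotate_probes(probes, g)
  # center 9524 is inside [9500, 10100]; center 9498 is one base outside
  expect_equal(ann$probe_center, c(9524L, 9498L))
  expect_equal(ann$label, c("gX", "NO ANNO"))
})

test_that("a divergent gene pair reports both genes, one per strand", {
  genes <- gene_table(c("gMinus", "gPlus"), c(8800L, 10000L),
                      c(9801L, 11000L), c("-", "+"))
  g <- genome_model("chr", 50000L, circular = FALSE, genes = genes)
  # gMinus tss = 9800, window [9700, 10300]; gPlus tss = 10000,
  # window [9500, 10100]; center 9900 lies in both
  ann <- annotate_probes(tibble::tibble(start = 9876L, end = 9926L), g)
  expect_equal(ann$probe_center, 9900L)
  expect_setequal(ann$gene_ids[[1]], c("gMinus", "gPlus"))
  expect_equal(ann$label, "gPlus,gMinus")
})

test_that("annotation matches the brute-force containment oracle", {
  set.seed(77)
  for (rep in 1:15) {
    g <- random_genome(sample(20:80, 1), 20000L,
                       circular = sample(c(TRUE, FALSE), 1))
    probes <- tile_probes(20000L, 50L)
    keep <- sort(sample.int(nrow(probes), 150L))
    probes <- probes[keep, ]
    ann <- annotate_probes(probes, g)
    oracle <- brute_annotate_ids(ann$probe_center, g)
    for (j in seq_along(oracle)) {
      expect_setequal(ann$gene_ids[[j]], oracle[[j]])
    }
  }
})

test_that("no annotation record carries two genes on the same strand", {
  set.seed(123)
  # deliberately crowded genome so many windows overlap
  g <- random_genome(150L, 15000L)
  probes <- tile_probes(15000L, 50L)
  ann <- annotate_probes(probes, g)
  for (ids in ann$gene_ids) {
    expect_lte(length(ids), 2L)
    if (length(ids) == 2L) {
      strands <- g$genes$strand[match(ids, g$genes$gene_id)]
      expect_setequal(strands, c("+", "-"))
    }
  }
})

test_that("annotation is invariant under genome reflection", {
  set.seed(55)
  L <- 20000L
  for (rep in 1:5) {
    g <- random_genome(40L, L, circular = TRUE)
    # odd-width probes: the center coordinate reflects exactly
    starts <- sort(sample.int(L - 51L, 200L)) - 1L
    probes <- tibble::tibble(start = starts, end = starts + 51L)
    ann <- annotate_probes(probes, g)

    flip <- c("+" = "-", "-" = "+")
    g_ref <- genome_model(
      g$name, L, circular = TRUE,
      genes = gene_table(g$genes$gene_id, L - g$genes$end,
                         L - g$genes$start, unname(flip[g$genes$strand]))
    )
    probes_ref <- tibble::tibble(start = L - probes$end,
                                 end = L - probes$start)
    ann_ref <- annotate_probes(probes_ref, g_ref)
    # reflected probe j corresponds to original probe j (same row order)
    expect_equal(ann_ref$probe_center, L - 1L - ann$probe_center)
    for (j in seq_len(nrow(ann))) {
      expect_setequal(ann_ref$gene_ids[[j]], ann$gene_ids[[j]])
    }
  }
})
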