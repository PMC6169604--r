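# reconstruct fragment midpoints from a read table in which circular
# fragments are junction-split into two rows per read_id
fragment_midpoints <- function(reads, L) {
  vapply(split(reads, reads$read_id), function(df) {
    len <- sum(df$end - df$start)
    s <- if (nrow(df) == 1L) df$start else df$start[df$end == L]
    as.integer((s + len %/% 2L) %% L)
  }, integer(1))
}

test_that("genome generation is deterministic and honors n_genes", {
  cfg <- simulation_config(genome_length = 200000L, n_genes = 50L, seed = 1L)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g1, f1)
  write_gff3(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(nrow(g1$genes), 50L)
  expect_true(all(c("+", "-") %in% g1$genes$strand))
  # non-overlapping placement
  o <- order(g1$genes$start)
  expect_true(all(g1$genes$start[o][-1] >= g1$genes$end[o][-50]))

  empty <- make_genome(simulation_config(n_genes = 0L))
  expect_equal(nrow(empty$genes), 0L)
})

test_that("read simulation is deterministic per (condition, seed) and
           conserves the read count", {
  demo <- demo_simulation(seed = 3L, n_reads = 5000L)
  r1 <- simulate_reads(demo$genome, demo$config, "WT")
  r2 <- simulate_reads(demo$genome, demo$config, "WT")
  expect_identical(r1, r2)
  expect_equal(n_unique_reads(r1), 5000L)
  rm <- simulate_reads(demo$genome, demo$config, "mutant")
  expect_false(identical(r1$start, rm$start))

  lens <- tapply(r1$end - r1$start, r1$read_id, sum)
  expect_true(all(lens >= 300 & lens <= 500))
  expect_true(all(r1$unique))

  expect_error(simulate_reads(demo$genome, demo$config, "absent"),
               "missing")
  cfg0 <- simulation_config(n_reads_per_condition = 0L)
  expect_equal(nrow(simulate_reads(make_genome(cfg0), cfg0, "any")), 0L)
})

test_that("background-only reads are uniform over the genome", {
  cfg <- simulation_config(genome_length = 200000L, n_genes = 0L,
                           n_reads_per_condition = 10000L, seed = 5L)
  g <- make_genome(cfg)
  reads <- simulate_reads(g, cfg, "bg")
  # pool to 2 kb bins (>> fragment length, so bin counts are effectively
  # independent) and test goodness of fit against the uniform null
  mids <- fragment_midpoints(reads, cfg$genome_length)
  bins <- table(cut(mids, breaks = seq(0, 200000, by = 2000),
                    include.lowest = TRUE))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("planted fold is recovered as the in/out probe count ratio", {
  cfg <- simulation_config(
    genome_length = 200000L, n_genes = 0L, n_reads_per_condition = 200000L,
    enrichments = list(enrichment_spec(100000L, 500L, c(A = 10))),
    seed = 8L)
  g <- make_genome(cfg)
  reads <- simulate_reads(g, cfg, "A")
  probes <- tile_probes(200000L, 50L)
  counts <- count_reads(probes, reads)
  centers <- probe_center(probes$start, probes$end)
  inside <- centers >= 99500 & centers < 100500
  # keep a smear margin around the window out of the background estimate
  margin <- centers >= 99000 & centers < 101000
  ratio <- mean(counts[inside]) / mean(counts[!margin])
  expect_gt(ratio, 7)
  expect_lt(ratio, 13)
})

test_that("two conditions with identical folds are exchangeable", {
  cfg <- simulation_config(
    genome_length = 100000L, n_genes = 0L, n_reads_per_condition = 20000L,
    enrichments = list(enrichment_spec(50000L, 500L, c(A = 1, B = 1))),
    seed = 13L)
  g <- make_genome(cfg)
  ta <- probe_track(g, simulate_reads(g, cfg, "A"))
  tb <- probe_track(g, simulate_reads(g, cfg, "B"))
  p <- suppressWarnings(
    stats::ks.test(ta$probes$percent, tb$probes$percent)$p.value)
  expect_gt(p, 0.001)
})

test_that("the truth table is a pure function of the config", {
  demo <- demo_simulation(seed = 2L, n_reads = 100L)
  tt <- truth_table(demo$config)
  expect_equal(nrow(tt), 6L)  # 3 loci x 2 conditions
  expect_identical(tt, truth_table(demo$config))
  expect_false(any(tt$background))

  cfg <- simulation_config(
    enrichments = list(enrichment_spec(1000L, 100L, c(A = 1, B = 1))))
  expect_true(all(truth_table(cfg)$background))
  expect_equal(nrow(truth_table(simulation_config())), 0L)
})

test_that("the demo plants one differential locus at a gene promoter", {
  demo <- demo_simulation(seed = 4L, n_reads = 100L)
  tt <- truth_table(demo$config)
  diffloc <- tt[tt$locus_id == "prom_diff", ]
  expect_equal(sort(diffloc$expected_fold), c(1, 10))
  gene <- demo$genome$genes[demo$genome$genes$gene_id == demo$diff_gene_id, ]
  d <- abs(diffloc$center[1] - gene$tss)
  expect_lte(min(d, demo$genome$length - d), 200L)
})
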