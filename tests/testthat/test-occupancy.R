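test_that("probe tiling covers the genome with a truncated final probe", {
  p <- tile_probes(1000L, 50L)
  expect_equal(nrow(p), 20L)
  expect_true(all(p$end - p$start == 50L))

  p <- tile_probes(1001L, 50L)
  expect_equal(nrow(p), 21L)
  expect_equal(c(p$start[21], p$end[21]), c(1000L, 1001L))

  # genome-scale ceiling arithmetic
  expect_equal(nrow(tile_probes(4042929L, 50L)), 80859L)

  # tiling invariant: no gaps, no overlaps
  p <- tile_probes(1234L, 50L)
  expect_equal(p$start[-1], p$end[-nrow(p)])
  expect_equal(p$start[1], 0L)
  expect_equal(p$end[nrow(p)], 1234L)

  expect_error(tile_probes(0L, 50L), "positive")
  expect_error(tile_probes(1000L, 0L), "positive")
})

test_that("a read increments every probe it overlaps by at least 1 bp", {
  probes <- tile_probes(200L, 50L)
  r <- aligned_reads("chr", 0L, 100L, "+")
  expect_equal(count_reads(probes, r), c(1L, 1L, 0L, 0L))
  r <- aligned_reads("chr", 10L, 40L, "+")
  expect_equal(count_reads(probes, r), c(1L, 0L, 0L, 0L))
  # 1 bp overlap at a probe boundary still counts
  r <- aligned_reads("chr", 49L, 51L, "+")
  expect_equal(count_reads(probes, r), c(1L, 1L, 0L, 0L))
})

test_that("non-unique reads are excluded and out-of-range reads rejected", {
  probes <- tile_probes(200L, 50L)
  r <- aligned_reads("chr", c(0L, 60L), c(50L, 100L), "+",
                     unique = c(TRUE, FALSE))
  expect_equal(count_reads(probes, r), c(1L, 0L, 0L, 0L))
  bad <- aligned_reads("chr", 150L, 260L, "+")
  expect_error(count_reads(probes, bad, genome_length = 200L,
                           circular = FALSE), "linear")
})

test_that("counting matches the brute-force all-pairs scan", {
  set.seed(42)
  probes <- tile_probes(10000L, 50L)
  reads <- random_reads(1000, 10000L)
  reads$unique[sample.int(1000, 50)] <- FALSE
  expect_equal(count_reads(probes, reads), brute_count(probes, reads))

  # permuting read order never changes any count
  perm <- reads[sample.int(nrow(reads)), ]
  expect_equal(count_reads(probes, perm), count_reads(probes, reads))
})

test_that("percent normalization is percent of total unique reads", {
  expect_equal(percent_normalize(c(2L, 8L), 10L), c(20, 80))
  expect_error(percent_normalize(c(-1L), 10L), "non-negative")
  expect_warning(p <- percent_normalize(c(3L, 4L), 0L), "0")
  expect_equal(p, c(0, 0))
})

test_that("percent columns conserve mass given the overlap rule", {
  g <- genome_model("chr", 1000L, circular = FALSE)
  # reads contained in single probes: percents sum to exactly 100
  contained <- aligned_reads("chr", c(0L, 55L, 910L), c(40L, 95L, 945L), "+")
  tr <- probe_track(g, contained)
  expect_equal(sum(tr$probes$percent), 100)
  # boundary-spanning reads contribute to >1 probe: sum exceeds 100
  spanning <- aligned_reads("chr", c(0L, 40L), c(40L, 140L), "+")
  tr <- probe_track(g, spanning)
  expect_gt(sum(tr$probes$percent), 100)
})

test_that("duplicating reads doubles counts and preserves percents", {
  set.seed(7)
  g <- genome_model("chr", 5000L, circular = FALSE)
  reads <- random_reads(200, 5000L, reference = "chr")
  doubled <- reads
  doubled$read_id <- paste0(doubled$read_id, "_dup")
  both <- dplyr::bind_rows(reads, doubled)
  t1 <- probe_track(g, reads)
  t2 <- probe_track(g, both)
  expect_equal(t2$probes$count, 2L * t1$probes$count)
  expect_equal(t2$total_unique_reads, 2L * t1$total_unique_reads)
  expect_equal(t2$probes$percent, t1$probes$percent)
})
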