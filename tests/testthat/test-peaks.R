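test_that("an all-equal track has sd 0 and zero candidates", {
  track <- track_from_percent(rep(3.5, 100))
  cut <- compute_cutoff(track)
  expect_equal(cut$cutoff, 3.5)
  expect_length(call_candidates(track, cut$cutoff), 0L)
})

test_that("cutoff matches an independently coded mean + 2 sd", {
  x <- c(1, 1, 1, 1, 6)
  track <- track_from_percent(x)
  cut <- compute_cutoff(track)
  # independent route: explicit n-1 formula, no stats::sd
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(cut$mean, 2)
  expect_equal(cut$sd, sqrt(5))
  expect_equal(cut$cutoff, m + 2 * s)
  expect_equal(cut$cutoff, 2 + 2 * sqrt(5))
  # 6 < 6.472...: strict inequality keeps it out of the candidate set
  expect_length(call_candidates(track, cut$cutoff), 0L)
  expect_error(compute_cutoff(track_from_percent(1)), "2 probes")
})

test_that("Gaussian track yields the 2-sd upper-tail candidate fraction", {
  set.seed(202)
  track <- track_from_percent(stats::rnorm(1e5, mean = 10, sd = 1))
  cut <- compute_cutoff(track)
  frac <- length(call_candidates(track, cut$cutoff)) / 1e5
  expect_lt(abs(frac - 0.0228), 0.003)
})

test_that("candidate selection equals a brute-force filter", {
  set.seed(9)
  track <- track_from_percent(stats::rexp(500))
  cut <- compute_cutoff(track)$cutoff
  expect_equal(call_candidates(track, cut),
               which(vapply(track$probes$percent, function(p) p > cut,
                            logical(1))))
  expect_length(call_candidates(track, max(track$probes$percent)), 0L)
  expect_equal(call_candidates(track, -1), seq_len(500L))
})

test_that("consecutive candidates merge into maximal runs", {
  probes <- tile_probes(1000L, 50L)
  # 1-based indices 4,5,6 are probes [150,300); index 10 is [450,500)
  peaks <- merge_candidates(c(4L, 5L, 6L, 10L), probes)
  expect_equal(peaks$start, c(150L, 450L))
  expect_equal(peaks$end, c(300L, 500L))
  expect_equal(peaks$n_probes, c(3L, 1L))

  expect_equal(nrow(merge_candidates(integer(), probes)), 0L)
  all_peaks <- merge_candidates(seq_len(20L), probes)
  expect_equal(nrow(all_peaks), 1L)
  expect_equal(c(all_peaks$start, all_peaks$end), c(0L, 1000L))
})

test_that("merging is idempotent", {
  set.seed(31)
  probes <- tile_probes(5000L, 50L)
  cand <- sort(sample.int(100L, 40L))
  peaks <- merge_candidates(cand, probes)
  # re-derive the candidate indices covered by the merged peaks and merge
  # again: nothing changes
  covered <- which(probes$start >= 0 &
                     vapply(seq_len(nrow(probes)), function(i) {
                       any(probes$start[i] >= peaks$start &
                             probes$end[i] <= peaks$end)
                     }, logical(1)))
  expect_equal(merge_candidates(covered, probes), peaks)
})

test_that("raising a probe never drops it from the set at fixed cutoff", {
  set.seed(13)
  x <- stats::runif(200)
  track <- track_from_percent(x)
  cut <- 0.8
  before <- call_candidates(track, cut)
  for (i in c(1L, 50L, 177L)) {
    y <- x
    y[i] <- y[i] + 0.5
    after <- call_candidates(track_from_percent(y), cut)
    expect_true(all(before %in% c(after, i)))
    expect_true(i %in% after || y[i] <= cut)
  }
})

test_that("call_peaks reports per-peak maxima over merged runs", {
  x <- rep(0.1, 60)
  x[20:23] <- c(4, 5, 4, 4)
  x[40] <- 4
  track <- track_from_percent(x)
  pc <- call_peaks(track)
  # cutoff for this track is ~2.6%, so both plateaus clear it whole
  expect_equal(nrow(pc$peaks), 2L)
  expect_equal(pc$peaks$max_percent, c(5, 4))
  expect_equal(pc$candidates, c(20:23, 40L))
  expect_equal(pc$cutoff, pc$mean + 2 * pc$sd)
})
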