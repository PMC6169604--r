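# Independent brute-force oracles and random-instance builders. These stay
# deliberately naive (all-pairs loops, direct distance arithmetic) so they
# check the vectorized implementations by a different route.

# all-pairs overlap scan: read counts toward every probe it overlaps >=1 bp
brute_count <- function(probes, reads) {
  reads <- reads[reads$unique, , drop = FALSE]
  vapply(seq_len(nrow(probes)), function(i) {
    sum(reads$start < probes$end[i] & reads$end > probes$start[i])
  }, integer(1))
}

# direct per-(probe, gene) containment test via oriented TSS distance:
# center is inside the promoter window iff the signed distance d from the
# TSS, measured in the direction of transcription (wrapped to (-L/2, L/2]
# on circular genomes), satisfies -upstream <= d <= downstream
brute_annotate_ids <- function(centers, genome, upstream = 500,
                               downstream = 100) {
  genes <- genome$genes
  L <- genome$length
  lapply(centers, function(center) {
    ids <- character(0)
    for (s in c("+", "-")) {
      idx <- which(genes$strand == s)
      if (length(idx) == 0) next
      d_raw <- if (s == "+") center - genes$tss[idx] else genes$tss[idx] - center
      d <- if (genome$circular) ((d_raw + L %/% 2) %% L) - L %/% 2 else d_raw
      inside <- d >= -upstream & d <= downstream
      if (any(inside)) {
        k <- idx[inside]
        dist <- abs(center - genes$tss[k])
        if (genome$circular) dist <- pmin(dist, L - dist)
        ids <- c(ids, genes$gene_id[k][which.min(dist)])
      }
    }
    ids
  })
}

# random genome with possibly crowded genes (annotation stress case)
random_genome <- function(n_genes, length = 20000L, circular = TRUE,
                          name = "rg") {
  starts <- sort(sample.int(length - 1200L, n_genes))
  lens <- sample(200:1000, n_genes, replace = TRUE)
  genome_model(
    name, length, circular = circular,
    genes = gene_table(sprintf("g%03d", seq_len(n_genes)), starts,
                       pmin(starts + lens, length),
                       sample(c("+", "-"), n_genes, replace = TRUE))
  )
}

random_reads <- function(n, genome_length, max_len = 500L,
                         reference = "rg", unique = TRUE) {
  lens <- sample(50:max_len, n, replace = TRUE)
  starts <- vapply(lens, function(l) {
    sample.int(genome_length - l, 1L) - 1L
  }, integer(1))
  aligned_reads(reference = reference, start = starts, end = starts + lens,
                strand = sample(c("+", "-"), n, replace = TRUE),
                unique = unique)
}

# probe track built directly from a percent vector, for cutoff/differential
# unit tests that do not need reads
track_from_percent <- function(percent, probe_width = 50L,
                               genome_name = "toy", total = 1000L,
                               counts = NULL) {
  probes <- tile_probes(length(percent) * probe_width, probe_width)
  probes$count <- if (is.null(counts)) rep(0L, length(percent)) else counts
  probes$percent <- percent
  chipocc:::new_probe_track(genome_name, length(percent) * probe_width,
                            probe_width, probes, total)
}
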