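#!/usr/bin/env Rscript
# Stage 2 — probe quantitation.
#
# Re-reads the simulated genome and read sets from results/, tiles the
# genome into 50 bp probes, counts uniquely mapped reads per probe
# (any-overlap rule) and normalizes each probe to percent of the total
# uniquely mapped reads of its sample.

library(chipocc)

out <- "results"
genome <- read_gff3(file.path(out, "genome.gff3"))

for (cond in c("WT", "mutant")) {
  reads <- read_alignments(file.path(out, sprintf("reads_%s.bed", cond)),
                           genome)
  track <- probe_track(genome, reads, probe_width = 50L)
  write_probe_table(track, file.path(out, sprintf("probes_%s.tsv", cond)))
  cat(sprintf(
    "%s: %d unique reads over %d probes; mean %.4g%%, max %.4g%% -> probes_%s.tsv\n",
    cond, track$total_unique_reads, nrow(track$probes),
    mean(track$probes$percent), max(track$probes$percent), cond))
}
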