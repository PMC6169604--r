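#!/usr/bin/env Rscript
# Stage 1 — synthetic study data.
#
# Builds the reference simulation: a 200 kb circular genome with 50 genes
# and two ChIP conditions (WT, mutant) of 1e5 reads each, with three
# planted enrichment windows at fold 10 — an origin-like intergenic locus
# and a promoter-proximal locus enriched in both conditions, and one
# promoter-proximal locus enriched only in the mutant (the differential
# target). Everything downstream runs from the files written here.

library(chipocc)

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

demo <- demo_simulation(seed = seed)
genome <- demo$genome
truth <- truth_table(demo$config)

write_gff3(genome, file.path(out, "genome.gff3"))
write_result_table(truth, file.path(out, "truth.tsv"),
                   list(seed = seed))

for (cond in c("WT", "mutant")) {
  reads <- simulate_reads(genome, demo$config, cond)
  write_reads_bed(reads, file.path(out, sprintf("reads_%s.bed", cond)))
  cat(sprintf("%s: %d reads (%d unique) written\n", cond,
              n_unique_reads(reads), n_unique_reads(reads)))
}

cat(sprintf("genome: %d bp, %d genes -> %s/genome.gff3\n",
            genome$length, nrow(genome$genes), out))
cat(sprintf("planted loci (differential target: %s promoter):\n",
            demo$diff_gene_id))
print(as.data.frame(truth))
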