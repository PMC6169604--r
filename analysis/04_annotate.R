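#!/usr/bin/env Rscript
# Stage 4 — promoter annotation.
#
# Each candidate probe (union over the two conditions) is assigned to the
# gene(s) whose promoter window — 500 bp upstream to 100 bp downstream of
# the TSS, oriented by gene strand — contains the probe center. Probes in
# divergent promoters can report one gene per strand; probes matching no
# window are labeled NO ANNO.

library(chipocc)

out <- "results"
genome <- read_gff3(file.path(out, "genome.gff3"))

cand <- lapply(c("WT", "mutant"), function(cond) {
  utils::read.delim(file.path(out, sprintf("candidates_%s.tsv", cond)),
                    comment.char = "#")
})
union_idx <- sort(unique(unlist(lapply(cand, `[[`, "probe_index"))))
probes <- tile_probes(genome$length, 50L)[union_idx, ]

ann <- annotate_probes(probes, genome, upstream = 500L, downstream = 100L)
ann_out <- ann
ann_out$gene_ids <- NULL
ann_out$probe_index <- union_idx
write_result_table(ann_out, file.path(out, "annotation.tsv"),
                   list(upstream = 500, downstream = 100))

n_anno <- sum(ann$label != "NO ANNO")
cat(sprintf("%d candidate probes in the union; %d annotated to a promoter, %d NO ANNO\n",
            nrow(ann), n_anno, nrow(ann) - n_anno))
cat("annotated genes:",
    paste(unique(unlist(ann$gene_ids)), collapse = ", "), "\n")
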