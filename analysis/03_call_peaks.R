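#!/usr/bin/env Rscript
# Stage 3 — peak calling.
#
# Per sample, the cutoff separating candidate peaks from background is the
# mean of all probe percents plus twice their standard deviation. Probes
# strictly above the cutoff are candidates; consecutive candidates merge
# into peaks, scored by their maximum probe percent.

library(chipocc)

out <- "results"

for (cond in c("WT", "mutant")) {
  track <- read_probe_table(file.path(out, sprintf("probes_%s.tsv", cond)))
  pc <- call_peaks(track, multiplier = 2)
  write_peaks_bed(pc, file.path(out, sprintf("peaks_%s.bed", cond)))
  cand <- pc$candidates
  write_result_table(
    tibble::tibble(probe_index = cand,
                   start = track$probes$start[cand],
                   end = track$probes$end[cand],
                   percent = track$probes$percent[cand]),
    file.path(out, sprintf("candidates_%s.tsv", cond)),
    list(cutoff = sprintf("%.17g", pc$cutoff)))
  cat(sprintf(
    "%s: cutoff %.4g%% (mean %.4g + 2 x sd %.4g); %d candidate probes in %d peaks\n",
    cond, pc$cutoff, pc$mean, pc$sd, length(cand), nrow(pc$peaks)))
  print(as.data.frame(pc$peaks))
}
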