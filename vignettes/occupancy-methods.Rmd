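---
title: "Methods: fixed-probe comparative ChIP-Seq occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-probe comparative ChIP-Seq occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chipocc` implements a deliberately simple, fully specified school of
ChIP-Seq analysis used for bacterial transcription-factor occupancy: no
input subtraction, no local background model, no FDR machinery — a fixed
probe grid, a global percent normalization, a global mean + 2·SD threshold,
a strand-aware promoter annotation, and a per-probe log2 ratio between two
conditions. This vignette explains each model choice, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical conventions.

## The quantitation model

The genome is subdivided into consecutive fixed-width probes (default
50 bp; the final probe is truncated at the genome end rather than dropped,
so the grid always tiles `[0, L)` exactly). Each uniquely mapped read
increments **every probe its interval overlaps by at least 1 bp**. The
overlap rule is a declared convention: with 300–500 bp fragments on a
50 bp grid, almost every read spans several probes, and any-overlap
counting is what fixed-grid quantitation tools do by default. Each probe's
count is then expressed as a percent of the **total number of uniquely
mapped reads** in the sample (not of the summed probe contributions), so
values are comparable between libraries of different depth. Column sums
therefore exceed 100 exactly when reads span probe boundaries; this is
intentional and tested.

Internally every coordinate is 0-based half-open. GFF3 and SAM (1-based
inclusive) are converted at the format boundary only; BED passes through
unchanged. A fragment spanning the origin junction of a circular
chromosome is stored as two intervals sharing one read identifier; totals
count distinct identifiers, so such a fragment is still one read.

Uniqueness cannot be re-derived from an alignment file that was already
filtered upstream, so the reader flags a SAM record as non-unique when it
carries either of the two standard multi-mapping signals: MAPQ 0 or an
`NH` tag above 1. BED reads are taken as unique.

## Peak calling

For one sample, the cutoff is

> cutoff = mean(percent) + 2 × sd(percent)

computed over **all** probes of that sample, with the n−1 (sample) SD
denominator. Each sample gets its own cutoff. A probe is a candidate when
its percent is **strictly** above the cutoff (ties at the cutoff are
background); maximal runs of consecutive candidates merge into peaks. Two
consequences worth knowing:

- On a pure-noise Gaussian track the candidate fraction is the 2-SD upper
  tail, ≈ 2.3%. The method is a signal-vs-background separator, not an
  error-rate control.
- Because enriched probes inflate both the mean and the SD, the cutoff is
  data-adaptive: stronger or wider planted signal raises it. On a track
  where all probes are equal the SD is 0 and nothing is called — the
  degenerate case resolves to "no peaks", not an error.

The SD-denominator choice (n−1 vs n) changes the cutoff by under 10⁻⁴
relative at genome scale; it is fixed here for reproducibility, not
because it matters numerically.

## Promoter annotation

A candidate probe is annotated with a gene when the **probe center** falls
within the window from 500 bp upstream to 100 bp downstream of the gene's
transcription start site, oriented by the gene's strand (for a minus-strand
gene the window is the mirror image). Both window ends are inclusive — the
window is read as a closed interval. The TSS is the strand-appropriate
extremity of the annotated gene span; operon-internal genes receive no
special treatment.

Conventions that are declared rather than derivable:

- For even-width probes the center is the left of the two middle bases,
  `floor((start + end − 1)/2)` — deterministic and at most 1 bp from any
  alternative convention.
- If windows of genes on **both** strands contain the center (a divergent
  promoter), both genes are reported; the record caps at two genes, one
  per strand. If several same-strand windows contain the center (dense
  synthetic genomes; essentially impossible on a real bacterial genome at
  −500/+100), the gene with the nearest TSS on that strand is kept.
- Probes matching no window are labeled `NO ANNO`.

On circular genomes windows wrap across the origin; on linear genomes they
clip. The annotation logic is verified against a brute-force per-(probe,
gene) containment oracle that computes oriented TSS distances directly,
and against a genome-reflection symmetry property.

## Differential occupancy

Two percent-normalized tracks on the same grid are compared probe-by-probe
by

> log2 ratio = log2(percent_alt + ε) − log2(percent_ref + ε)

Computing the difference of logarithms (rather than the log of the
quotient) makes condition swap negate every value bit-exactly. The
pseudocount ε guards zero-coverage probes; its default is one read's
percent equivalent in the shallower library, `100 / min(total_ref,
total_alt)`, so it scales with depth instead of being an arbitrary
constant. |log2 ratio| is non-increasing in ε (tested), so a larger guard
only ever attenuates. Percent normalization is the only depth correction
applied — the method's stated normalization — and no significance test is
attached to the ratios; the output is a magnitude ranking. Probes that are
candidates in at least one condition, ranked by |log2 ratio| with
coordinate tie-breaks, form the target table.

## The synthetic-data generator

The generator provides ground truth the analysis can be held to. It
emulates, per condition: a circular bacterial chromosome (default 200 kb —
a scaled-down stand-in chosen so that a full two-condition run takes
seconds, with ~4000 probes, enough for stable mean/SD estimation) carrying
50 non-overlapping genes of 600–1500 bp on both strands; an IP library of
1e5 fragments whose midpoints are drawn from a mixture of a uniform
background over the whole genome and planted windows, each window's extra
mass proportional to (fold − 1) × width so the expected midpoint density
inside a window is exactly `fold` times background; and fragment lengths
uniform on 300–500 bp, the shearing target of the emulated protocol.
Fragment **midpoints** (not 5′ ends) are the enriched coordinate, since
crosslinking enrichment is symmetric about the bound site. Each
(condition, seed) pair gets its own RNG stream, so per-condition output is
reproducible regardless of evaluation order, and the entire output is a
pure function of the configuration.

The reference two-condition dataset plants three windows at fold 10: an
origin-like locus in the largest intergenic gap and one promoter-proximal
locus enriched in both conditions, and one promoter-proximal locus
enriched only in the mutant (fold 10 vs 1) — the differential target.
Promoter-proximal windows are centered 200 bp upstream of a gene's TSS,
inside the annotation window.

Planted windows default to half-width 2000 bp, emulating a region of
clustered binding sites rather than a single footprint. The width is a
resolution argument: observed coverage smears roughly half a fragment
length (~150–250 bp) beyond the region of enriched midpoints, so the truth
window must be wide relative to that smear for "called peak bases lie
inside planted windows" to be a meaningful specificity measure. With 4 kb
windows the called peaks are ≥ 95% inside truth regions; with windows
comparable to the fragment length the same pipeline would look falsely
unspecific, because the smear — a property of the assay, not a defect of
the caller — would dominate.

What the generator does **not** emulate: sequencing error, GC and
mappability bias, non-uniform input coverage (the background is uniform
because no input model is part of the method, and uniform is the null that
makes mean + 2·SD meaningful), replicate structure, and multi-replicon
genomes. Passing the planted-truth suite therefore demonstrates that the
pipeline's arithmetic and logic are correct, not that the mean + 2·SD rule
is robust to the biases of real libraries.

A note on testing uniformity: per-probe counts of a background-only
library are marginally Poisson but correlated between adjacent probes (one
fragment spans ~8 probes), which would break a chi-square test at 50 bp
resolution. The goodness-of-fit check therefore pools fragment midpoints
into 2 kb bins, where the independence assumption holds.

## Assay calculations

The qChIP module fits the standard curve Ct = slope · log10(quantity) +
intercept by least squares to a serially diluted chromatin input
(quantities in relative units; the undiluted input aliquot is 1). An IP
sample's quantity is interpolated as `10^((Ct − intercept)/slope)`. The
aliquot is a fraction (default 10%) of the total chromatin, so

> % input = 100 × q_IP × input_fraction

The input-fraction correction is exposed as a parameter rather than
hard-coded, since published % input values do not always state whether it
was applied. Amplification efficiency `10^(−1/slope) − 1` is reported as a
diagnostic but never used to correct quantities — curve interpolation
already embeds it. A forward simulator (`simulate_ct()`) generates Ct
values at known efficiency and noise so that curve fitting and inversion
are testable: at zero noise the round trip recovers quantities to machine
precision, and at σ(Ct) = 0.1 the efficiency is recovered within ±0.05.

Miller units are the exact formula `U = (A420 × 1000)/(A660 × t × v)`
with `t` in minutes and `v` in mL; replicates aggregate to mean ±
SE = sd/√n.

## Numerical and degenerate-input conventions

- Strict `>` at the peak cutoff; SD with n−1; cutoff on percent values
  (normalization precedes thresholding).
- A zero-read sample normalizes to all-zero percents with a warning, not
  an error; an empty candidate set merges to an empty peak list.
- Probe tables serialize percents at full precision (`%.17g`) so
  write-then-read is bit-exact; all outputs carry a `# key=value` header
  naming the pipeline version and parameters, and repeated runs under one
  seed are byte-identical.
- Grid mismatches between compared tracks (length, width, genome name)
  are hard errors naming the first differing probe, never silently
  recycled.

## Problem sizes used by the test suite

The oracle-equivalence suites run on 10 kb genomes with up to 2000 reads
and up to 200 genes (50 random instances each); the planted-recovery and
determinism checks run the full reference simulation (200 kb, 2 × 1e5
reads). These sizes give stable statistics while keeping a complete run of
the suite under a minute on one core.

## Known limitations

- The mean + 2·SD rule has no error-rate interpretation and is sensitive
  to the fraction of the genome that is enriched; it is implemented
  because it is the method specified, not because it is recommended
  practice for eukaryotic-scale data.
- Single comparative runs only: no replicate-aware statistics.
- BAM input is out of scope (SAM and BED are supported); alignment and
  read QC happen upstream.
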