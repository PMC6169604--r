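Package: chipocc
Title: Comparative ChIP-Seq Occupancy on Fixed-Width Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies transcription-factor occupancy from aligned ChIP-Seq
    reads on a fixed 50 bp probe grid, normalizes each probe to percent of
    total uniquely mapped reads, calls candidate peaks with a mean plus
    twice-standard-deviation cutoff, annotates candidates to genes through a
    strand-aware -500/+100 window around the transcription start site, and
    compares two conditions by per-probe log2 ratio. Includes a synthetic
    read generator with planted enrichment for ground-truth validation, and
    the companion bench-assay calculations (qPCR percent-input via a Ct
    standard curve, beta-galactosidase Miller units).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
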