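#' Tile a genome into fixed-width probes
#'
#' The quantitation grid: the genome is subdivided into consecutive
#' `probe_width` bp probes (50 bp by default). Probes tile `[0, length)`
#' without gaps or overlaps; the final probe is truncated at the genome end
#' rather than dropped, preserving the full tiling.
#'
#' @param genome_length genome length in bp (> 0).
#' @param probe_width probe width in bp (> 0), default 50.
#' @return A tibble with columns `start`, `end` (0-based half-open),
#'   `ceiling(genome_length / probe_width)` rows.
#' @export
tile_probes <- function(genome_length, probe_width = 50L) {
  genome_length <- as.integer(genome_length)
  probe_width <- as.integer(probe_width)
  if (is.na(genome_length) || genome_length <= 0L) {
    stop("genome_length must be a positive integer")
  }
  if (is.na(probe_width) || probe_width <= 0L) {
    stop("probe_width must be a positive integer")
  }
  starts <- seq.int(0L, genome_length - 1L, by = probe_width)
  tibble::tibble(start = starts,
                 end = pmin.int(starts + probe_width, genome_length))
}

#' Count reads per probe
#'
#' Every uniquely mapped read increments every probe its interval overlaps
#' by at least 1 bp. Non-unique reads are excluded before counting. The
#' result is independent of read order.
#'
#' @param probes probe tibble from [tile_probes()].
#' @param reads an [aligned_reads()] tibble.
#' @param genome_length genome length; on a linear genome a read outside
#'   `[0, genome_length)` is a hard error (on a circular genome wrapping
#'   fragments are expected to arrive pre-split into in-range intervals).
#' @param circular is the genome circular?
#' @return Integer vector of counts, one per probe.
#' @export
count_reads <- function(probes, reads, genome_length = max(probes$end),
                        circular = TRUE) {
  reads <- reads[reads$unique, , drop = FALSE]
  if (any(reads$start < 0L) || any(reads$end > genome_length)) {
    if (!circular) {
      stop("read interval outside [0, ", genome_length, ") on a linear genome")
    }
    stop("read interval outside [0, ", genome_length,
         "); split wrapping fragments before counting")
  }
  probe_ir <- IRanges::IRanges(start = probes$start + 1L, end = probes$end)
  read_ir <- IRanges::IRanges(start = reads$start + 1L, end = reads$end)
  as.integer(IRanges::countOverlaps(probe_ir, read_ir, minoverlap = 1L))
}

new_probe_track <- function(genome_name, genome_length, probe_width, probes,
                            total_unique_reads) {
  structure(
    list(genome_name = genome_name,
         genome_length = as.integer(genome_length),
         probe_width = as.integer(probe_width),
         probes = probes,
         total_unique_reads = as.integer(total_unique_reads)),
    class = "probe_track"
  )
}

#' Normalize probe counts to percent of total unique reads
#'
#' The relative abundance of each probe is expressed as a percent of the
#' total uniquely mapped reads in the sample:
#' `percent[i] = 100 * counts[i] / total_unique_reads`. The denominator is
#' the number of reads ingested, not the sum of probe contributions, so a
#' read overlapping two probes contributes to both and column sums may
#' exceed 100.
#'
#' @param counts non-negative integer vector.
#' @param total_unique_reads total uniquely mapped reads in the sample; 0
#'   yields all-zero percents with a warning.
#' @return Numeric vector of percents.
#' @export
percent_normalize <- function(counts, total_unique_reads) {
  if (any(counts < 0) || total_unique_reads < 0) {
    stop("counts and total_unique_reads must be non-negative")
  }
  if (total_unique_reads == 0) {
    warning("total_unique_reads is 0; all percents set to 0")
    return(rep(0, length(counts)))
  }
  100 * counts / total_unique_reads
}

#' Quantify occupancy of a read set on the probe grid
#'
#' Convenience wrapper running the full per-sample quantitation: tile,
#' count uniquely mapped reads per probe, and percent-normalize against the
#' distinct unique-read total.
#'
#' @param genome a [genome_model()].
#' @param reads an [aligned_reads()] tibble on that genome.
#' @param probe_width probe width in bp, default 50.
#' @return A `probe_track` object: probe grid with `count` and `percent`
#'   columns plus the sample's `total_unique_reads`.
#' @export
probe_track <- function(genome, reads, probe_width = 50L) {
  bad <- setdiff(base::unique(reads$reference), genome$name)
  if (length(bad) > 0) {
    stop("reads mapped to unknown reference(s): ", paste(bad, collapse = ", "))
  }
  probes <- tile_probes(genome$length, probe_width)
  counts <- count_reads(probes, reads, genome_length = genome$length,
                        circular = genome$circular)
  total <- n_unique_reads(reads)
  probes$count <- counts
  probes$percent <- percent_normalize(counts, total)
  new_probe_track(genome$name, genome$length, probe_width, probes, total)
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf(
    "<probe_track> %s: %d probes of %d bp, %d unique reads, max %.4g%%\n",
    x$genome_name, nrow(x$probes), x$probe_width, x$total_unique_reads,
    if (nrow(x$probes)) max(x$probes$percent) else NA_real_))
  invisible(x)
}
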