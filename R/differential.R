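#' Pair two probe tracks on a common grid
#'
#' Probe-wise pairing of a reference and an alternative condition. The two
#' tracks must share genome name, probe width and an identical probe grid;
#' any mismatch is a hard error naming the first differing probe.
#'
#' @param ref,alt two [probe_track()] objects.
#' @return Tibble with `start`, `end`, `count_ref`, `count_alt`,
#'   `percent_ref`, `percent_alt`; attributes carry the two read totals.
#' @export
align_tracks <- function(ref, alt) {
  if (ref$genome_name != alt$genome_name) {
    stop("genome names differ: ", ref$genome_name, " vs ", alt$genome_name)
  }
  if (ref$probe_width != alt$probe_width) {
    stop("probe widths differ: ", ref$probe_width, " vs ", alt$probe_width)
  }
  if (nrow(ref$probes) != nrow(alt$probes)) {
    stop("probe counts differ: ", nrow(ref$probes), " vs ", nrow(alt$probes))
  }
  diff <- which(ref$probes$start != alt$probes$start |
                ref$probes$end != alt$probes$end)
  if (length(diff) > 0) {
    stop("probe grids differ first at probe ", diff[1L], " ([",
         ref$probes$start[diff[1L]], ",", ref$probes$end[diff[1L]], ") vs [",
         alt$probes$start[diff[1L]], ",", alt$probes$end[diff[1L]], "))")
  }
  out <- tibble::tibble(
    start = ref$probes$start, end = ref$probes$end,
    count_ref = ref$probes$count, count_alt = alt$probes$count,
    percent_ref = ref$probes$percent, percent_alt = alt$probes$percent
  )
  attr(out, "total_ref") <- ref$total_unique_reads
  attr(out, "total_alt") <- alt$total_unique_reads
  out
}

#' Default pseudocount for log2 ratios
#'
#' One read's percent equivalent in the shallower of the two libraries,
#' `100 / min(total_ref, total_alt)`: a scale-aware guard against division
#' by zero at probes with no coverage.
#'
#' @param total_ref,total_alt unique-read totals of the two conditions.
#' @return Positive pseudocount in percent units.
#' @export
default_epsilon <- function(total_ref, total_alt) {
  stopifnot(total_ref > 0, total_alt > 0)
  100 / min(total_ref, total_alt)
}

#' Per-probe log2 occupancy ratio between two conditions
#'
#' The comparative occupancy statistic: for each probe,
#' `log2((percent_alt + eps) / (percent_ref + eps))`, computed as a
#' difference of logs so that swapping the two conditions negates every
#' value bit-exactly. No depth rescaling is applied beyond the percent
#' normalization already in the tracks.
#'
#' @param paired output of [align_tracks()].
#' @param epsilon pseudocount in percent units (> 0); default is
#'   [default_epsilon()] of the paired totals.
#' @return `paired` with an added `log2_ratio` column.
#' @export
log2_ratio <- function(paired, epsilon = NULL) {
  if (is.null(epsilon)) {
    epsilon <- default_epsilon(attr(paired, "total_ref"),
                               attr(paired, "total_alt"))
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("epsilon must be a single positive number")
  }
  paired$log2_ratio <- log2(paired$percent_alt + epsilon) -
    log2(paired$percent_ref + epsilon)
  attr(paired, "epsilon") <- epsilon
  paired
}

#' Build the differential occupancy table
#'
#' Pairs two tracks, computes per-probe log2 ratios, and joins the gene
#' annotation labels when provided.
#'
#' @param ref,alt two [probe_track()] objects on the same grid.
#' @param annotation optional [annotate_probes()] table for the same grid.
#' @param epsilon pseudocount, see [log2_ratio()].
#' @return Tibble of differential records, one row per probe.
#' @export
differential_table <- function(ref, alt, annotation = NULL, epsilon = NULL) {
  records <- log2_ratio(align_tracks(ref, alt), epsilon)
  if (!is.null(annotation)) {
    lab <- annotation$label[match(records$start, annotation$probe_start)]
    records$gene_ids <- ifelse(is.na(lab), "NO ANNO", lab)
  } else {
    records$gene_ids <- "NO ANNO"
  }
  records
}

#' Rank differential targets
#'
#' Restricts the differential records to probes that are candidate peaks in
#' at least one condition and sorts them by absolute log2 ratio,
#' descending; ties are broken by genome coordinate. This is the ranked
#' target list a comparative ChIP-Seq analysis reports.
#'
#' @param records a [differential_table()] (or [log2_ratio()]) tibble.
#' @param candidates_union integer probe indices that are candidates in at
#'   least one condition.
#' @return The ranked subset of `records`, with a `probe_index` column.
#' @export
rank_targets <- function(records, candidates_union) {
  candidates_union <- sort(base::unique(as.integer(candidates_union)))
  out <- records[candidates_union, , drop = FALSE]
  out$probe_index <- candidates_union
  out[order(-abs(out$log2_ratio), out$start), , drop = FALSE]
}
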