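#' Probe center coordinate
#'
#' The annotation anchor of a probe. For even-width probes the center is
#' the left of the two middle bases: `floor((start + end - 1) / 2)`. This
#' keeps the center an integer coordinate on the probe; the choice of the
#' left middle is a declared convention and matters at most 1 bp.
#'
#' @param start,end probe interval, 0-based half-open, vectorized.
#' @return Integer center coordinate(s).
#' @export
probe_center <- function(start, end) {
  stopifnot(all(start < end))
  as.integer((as.numeric(start) + as.numeric(end) - 1) %/% 2)
}

#' Promoter window of a gene
#'
#' The orientation-aware annotation window around the transcription start
#' site: from `upstream` bases before the TSS to `downstream` bases past
#' it, both ends inclusive, mirrored for minus-strand genes. On a linear
#' genome the window is clipped to `[0, genome_length - 1]`; on a circular
#' genome it wraps across the origin junction.
#'
#' @param tss TSS coordinate (0-based).
#' @param strand `"+"` or `"-"`.
#' @param upstream bases upstream of the TSS, default 500.
#' @param downstream bases downstream, default 100.
#' @param genome_length genome length for clipping/wrapping; `NULL` leaves
#'   the window unclipped.
#' @param circular wrap instead of clip when `TRUE`.
#' @return A list with inclusive bounds `lo`, `hi` and a `wraps` flag
#'   (`TRUE` when the window crosses the origin of a circular genome, in
#'   which case it covers `[lo, genome_length) U [0, hi]`).
#' @export
promoter_window <- function(tss, strand, upstream = 500L, downstream = 100L,
                            genome_length = NULL, circular = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") {
    lo <- tss - upstream
    hi <- tss + downstream
  } else {
    lo <- tss - downstream
    hi <- tss + upstream
  }
  wraps <- FALSE
  if (!is.null(genome_length)) {
    if (circular) {
      span <- hi - lo
      if (span >= genome_length) {          # window covers the whole genome
        lo <- 0L
        hi <- genome_length - 1L
      } else {
        lo <- lo %% genome_length
        hi <- hi %% genome_length
        wraps <- lo > hi
      }
    } else {
      lo <- max(lo, 0L)
      hi <- min(hi, genome_length - 1L)
    }
  }
  list(lo = as.integer(lo), hi = as.integer(hi), wraps = wraps)
}

window_contains <- function(win, x) {
  if (win$wraps) x >= win$lo | x <= win$hi else x >= win$lo & x <= win$hi
}

#' Annotate candidate probes to genes
#'
#' A probe is annotated with a gene when the probe center lies inside that
#' gene's promoter window ([promoter_window()]). When windows of genes on
#' both strands contain the center, both genes are reported (at most one
#' per strand); if several same-strand windows contain it, the gene whose
#' TSS is nearest on that strand is kept. Probes matching no window are
#' labeled `"NO ANNO"`.
#'
#' @param probes tibble of candidate probe intervals (`start`, `end`).
#' @param genome a [genome_model()] whose genes carry strand and TSS.
#' @param upstream,downstream window extent in bp, defaults 500 and 100.
#' @param centers optional explicit probe centers overriding
#'   [probe_center()] (used e.g. for symmetry checks).
#' @return Tibble with one row per probe: `probe_start`, `probe_end`,
#'   `probe_center`, `gene_ids` (list column, 0-2 ids), `label`
#'   (comma-joined ids or `"NO ANNO"`).
#' @export
annotate_probes <- function(probes, genome, upstream = 500L,
                            downstream = 100L, centers = NULL) {
  if (is.null(centers)) centers <- probe_center(probes$start, probes$end)
  genes <- genome$genes
  n <- nrow(probes)
  hits_id <- vector("list", n)
  if (nrow(genes) > 0 && n > 0) {
    L <- genome$length
    wins <- lapply(seq_len(nrow(genes)), function(i) {
      promoter_window(genes$tss[i], genes$strand[i], upstream, downstream,
                      genome_length = L, circular = genome$circular)
    })
    # circular TSS distance, for nearest-TSS tie-breaking within a strand
    tss_dist <- function(center, tss) {
      d <- abs(center - tss)
      if (genome$circular) pmin(d, L - d) else d
    }
    for (j in seq_len(n)) {
      inside <- vapply(wins, window_contains, logical(1), x = centers[j])
      ids <- character(0)
      for (s in c("+", "-")) {
        k <- which(inside & genes$strand == s)
        if (length(k) > 1L) {
          k <- k[which.min(tss_dist(centers[j], genes$tss[k]))]
        }
        if (length(k) == 1L) ids <- c(ids, genes$gene_id[k])
      }
      hits_id[[j]] <- ids
    }
  } else {
    hits_id <- rep(list(character(0)), n)
  }
  label <- vapply(hits_id, function(ids) {
    if (length(ids) == 0) "NO ANNO" else paste(ids, collapse = ",")
  }, "")
  tibble::tibble(
    probe_start = probes$start, probe_end = probes$end,
    probe_center = centers, gene_ids = hits_id, label = label
  )
}
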