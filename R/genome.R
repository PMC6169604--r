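#' Build a gene table
#'
#' Assembles a validated tibble of gene models in the package's internal
#' coordinate convention (0-based, half-open). The transcription start site
#' (TSS) is derived from the strand: the first transcribed base, i.e. `start`
#' for `+` genes and `end - 1` for `-` genes.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param start,end integer vectors; 0-based half-open span, `start < end`.
#' @param strand character vector of `"+"` / `"-"`.
#' @return A tibble with columns `gene_id`, `start`, `end`, `strand`, `tss`.
#' @export
gene_table <- function(gene_id, start, end, strand) {
  gene_id <- as.character(gene_id)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  if (length(start) != n || length(end) != n || length(strand) != n) {
    stop("gene_id, start, end and strand must have equal length")
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (any(!strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(start >= end)) {
    stop("gene start must be < end (0-based half-open)")
  }
  tss <- ifelse(strand == "+", start, end - 1L)
  tibble::tibble(gene_id = gene_id, start = start, end = end,
                 strand = strand, tss = as.integer(tss))
}

empty_gene_table <- function() {
  gene_table(character(), integer(), integer(), character())
}

#' Construct a genome model
#'
#' A genome model is the coordinate frame for the whole pipeline: a named
#' replicon of known length, a circularity flag (bacterial chromosomes are
#' typically circular), and an ordered gene table.
#'
#' @param name replicon name (the `reference` field of aligned reads must
#'   match it).
#' @param length genome length in bp (> 0).
#' @param circular logical; when `TRUE`, fragments and promoter windows may
#'   wrap across the origin junction.
#' @param genes a gene table from [gene_table()]; genes must lie within
#'   `[0, length)`.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(name, length, circular = TRUE,
                         genes = empty_gene_table()) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop("genome length must be a positive integer")
  stopifnot(is.character(name), nzchar(name))
  if (!all(c("gene_id", "start", "end", "strand", "tss") %in% names(genes))) {
    stop("genes must be a gene_table()")
  }
  if (nrow(genes) > 0) {
    if (any(genes$start < 0L) || any(genes$end > length)) {
      stop("all genes must lie within [0, genome length)")
    }
    genes <- genes[order(genes$start, genes$end), ]
  }
  structure(
    list(name = name, length = length, circular = isTRUE(circular),
         genes = genes),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %s: %s bp, %s, %d genes\n",
              x$name, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$genes)))
  invisible(x)
}

#' Assemble a table of aligned reads
#'
#' The countable unit of the pipeline: one mapped fragment interval in
#' 0-based half-open coordinates with a uniqueness flag. Only reads with
#' `unique = TRUE` are ever counted. A fragment spanning the circular origin
#' junction is stored as two rows sharing one `read_id`, so read totals are
#' counted over distinct `read_id`s, not rows.
#'
#' @param reference replicon name for every interval.
#' @param start,end 0-based half-open interval, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param unique logical; `FALSE` marks multi-mapping reads.
#' @param read_id identifier grouping split intervals of one fragment;
#'   defaults to one id per row.
#' @return A tibble with class `aligned_reads`.
#' @export
aligned_reads <- function(reference, start, end, strand,
                          unique = TRUE, read_id = NULL) {
  n <- length(start)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) stop("read start must be < end")
  if (any(!strand %in% c("+", "-"))) stop("read strand must be '+' or '-'")
  if (is.null(read_id)) read_id <- sprintf("read%d", seq_len(n))
  out <- tibble::tibble(
    reference = rep_len(as.character(reference), n),
    start = start, end = end,
    strand = as.character(strand),
    unique = rep_len(as.logical(unique), n),
    read_id = as.character(read_id)
  )
  class(out) <- c("aligned_reads", class(out))
  out
}

#' Number of distinct uniquely mapped reads
#'
#' The normalization denominator of percent occupancy: distinct `read_id`s
#' among rows flagged `unique`, so a junction-split fragment counts once.
#'
#' @param reads an [aligned_reads()] table.
#' @return integer count.
#' @export
n_unique_reads <- function(reads) {
  length(base::unique(reads$read_id[reads$unique]))
}
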