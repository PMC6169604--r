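## Format boundaries. Internal coordinates are 0-based half-open everywhere;
## GFF3 and SAM are 1-based inclusive, BED is already 0-based half-open.
## Conversion happens here and nowhere else.

#' Read gene models from GFF3
#'
#' Imports a GFF3 file via `rtracklayer` and converts it to the internal
#' 0-based half-open convention (`GFF3 start - 1`, end unchanged). Features
#' of type `gene` are used when present, otherwise all features. Records
#' without a strand are dropped with a warning; duplicate gene IDs are a
#' hard error. The genome length is taken from the `##sequence-region`
#' pragma.
#'
#' @param path GFF3 file.
#' @param circular is the replicon circular? (GFF3 does not carry this).
#' @return A [genome_model()].
#' @export
read_gff3 <- function(path, circular = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  # genome length comes from the ##sequence-region pragma (not surfaced by
  # the importer)
  pragma <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(pragma) != 1L) {
    stop("expected exactly one ##sequence-region pragma in ", path)
  }
  fields <- strsplit(trimws(pragma), "\\s+")[[1L]]
  if (length(fields) < 4L) stop("malformed ##sequence-region pragma: ", pragma)
  name <- fields[2L]
  len <- as.integer(fields[4L])

  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene")) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  strand <- as.character(BiocGenerics::strand(gr))
  unstranded <- !strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) without strand dropped")
    gr <- gr[!unstranded]
    strand <- strand[!unstranded]
  }
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  if (is.null(ids) || anyNA(ids)) stop("gene records must carry an ID attribute")
  genes <- gene_table(
    gene_id = as.character(ids),
    start = BiocGenerics::start(gr) - 1L,  # 1-based inclusive -> 0-based
    end = BiocGenerics::end(gr),
    strand = strand
  )
  genome_model(name, len, circular = circular, genes = genes)
}

#' Write a genome model to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open genes become 1-based
#' inclusive GFF3 `gene` records, with a `##sequence-region` pragma carrying
#' the genome length. Output is deterministic (no timestamps).
#'
#' @param genome a [genome_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", genome$name, genome$length)
  )
  if (nrow(g) > 0) {
    lines <- c(lines, sprintf(
      "%s\tchipocc\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      genome$name, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned reads from BED or SAM
#'
#' BED intervals are ingested as-is (BED is 0-based half-open); the name
#' column, when present, becomes `read_id` so junction-split fragments stay
#' grouped. SAM records are converted through `Rsamtools`/
#' `GenomicAlignments`: unmapped records are dropped, the reference span is
#' derived from the CIGAR, and a record is flagged non-unique when it has
#' MAPQ 0 or an `NH` tag greater than 1 (the standard multi-mapping
#' signals).
#'
#' @param path input file.
#' @param genome a [genome_model()]; reads on any other reference are a
#'   hard error.
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @return An [aligned_reads()] tibble.
#' @export
read_alignments <- function(path, genome, format = c("auto", "bed", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    refs <- as.character(GenomeInfoDb::seqnames(gr))
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids) || anyNA(ids) || !any(nzchar(ids))) {
      ids <- sprintf("read%d", seq_along(gr))
    }
    strand <- as.character(BiocGenerics::strand(gr))
    strand[!strand %in% c("+", "-")] <- "+"
    reads <- aligned_reads(
      reference = refs,
      start = BiocGenerics::start(gr) - 1L,  # GRanges 1-based -> 0-based
      end = BiocGenerics::end(gr),
      strand = strand,
      unique = TRUE,
      read_id = ids
    )
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
    aln <- GenomicAlignments::readGAlignments(
      bam,
      param = Rsamtools::ScanBamParam(
        what = c("mapq", "qname"),
        tag = "NH"
      )
    )
    mapq <- S4Vectors::mcols(aln)$mapq
    nh <- S4Vectors::mcols(aln)$NH
    non_unique <- (!is.na(mapq) & mapq == 0L) | (!is.na(nh) & nh > 1L)
    reads <- aligned_reads(
      reference = as.character(GenomeInfoDb::seqnames(aln)),
      start = BiocGenerics::start(aln) - 1L,  # SAM 1-based -> 0-based
      end = BiocGenerics::end(aln),
      strand = as.character(BiocGenerics::strand(aln)),
      unique = !non_unique,
      read_id = S4Vectors::mcols(aln)$qname
    )
  }
  bad <- setdiff(base::unique(reads$reference), genome$name)
  if (length(bad) > 0) {
    stop("reads mapped to unknown reference(s): ", paste(bad, collapse = ", "))
  }
  reads
}

#' Write reads as BED6
#'
#' One line per interval; the name column carries `read_id` so a
#' junction-split fragment re-groups on re-import.
#'
#' @param reads an [aligned_reads()] tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   reads$reference, reads$start, reads$end,
                   reads$read_id, 0L, reads$strand)
  writeLines(lines, path)
  invisible(path)
}

## Comment header written on every TSV output: pipeline version + the
## parameters needed to reproduce the file.
param_header <- function(params) {
  version <- as.character(utils::packageVersion("chipocc"))
  c(sprintf("# chipocc %s", version),
    sprintf("# %s=%s", names(params), vapply(params, as.character, "")))
}

#' Write a probe track as TSV
#'
#' Exports the quantified probe list: columns `probe_start`, `probe_end`,
#' `count`, `percent`, preceded by a `#` comment header naming the pipeline
#' version, genome, probe width and read total. Percents are serialized at
#' full double precision so [read_probe_table()] round-trips bit-exactly.
#'
#' @param track a [probe_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(track, path) {
  header <- param_header(list(
    genome_name = track$genome_name,
    genome_length = track$genome_length,
    probe_width = track$probe_width,
    total_unique_reads = track$total_unique_reads
  ))
  p <- track$probes
  body <- sprintf("%d\t%d\t%d\t%s", p$start, p$end, p$count,
                  sprintf("%.17g", p$percent))
  writeLines(c(header, "probe_start\tprobe_end\tcount\tpercent", body), path)
  invisible(path)
}

#' Read a probe track written by [write_probe_table()]
#'
#' @param path TSV file with the `#` parameter header.
#' @return A [probe_track()] equal to the one written.
#' @export
read_probe_table <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "# ")]
  kv <- regmatches(header, regexec("^# ([a-z_]+)=(.*)$", header))
  kv <- kv[lengths(kv) == 3L]
  params <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  for (field in c("genome_name", "genome_length", "probe_width",
                  "total_unique_reads")) {
    if (!field %in% names(params)) stop("probe table header lacks ", field)
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = c("integer", "integer", "integer",
                                          "numeric"))
  new_probe_track(
    genome_name = params[["genome_name"]],
    genome_length = as.integer(params[["genome_length"]]),
    probe_width = as.integer(params[["probe_width"]]),
    probes = tibble::tibble(start = tab$probe_start, end = tab$probe_end,
                            count = tab$count, percent = tab$percent),
    total_unique_reads = as.integer(params[["total_unique_reads"]])
  )
}

#' Write a generic result table as TSV with a parameter header
#'
#' @param df data frame to write.
#' @param path output file.
#' @param params named list recorded as `# key=value` comment lines.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(param_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
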