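## Synthetic ChIP data with planted ground truth. The generator emulates a
## small circular bacterial chromosome: genes on both strands, IP read sets
## made of a uniform background plus fold-enriched windows, and fragment
## lengths matching a 0.3-0.5 kbp shearing target.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Distinct reproducible stream per (condition, seed), independent of the
## order conditions are simulated in.
condition_seed <- function(seed, condition) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(condition))) %% 2147483647L
}

#' Declare a planted enrichment window
#'
#' One fold-enriched locus of the simulation: fragment midpoints inside
#' `[locus_center - half_width, locus_center + half_width)` are
#' over-represented by the condition's fold relative to the uniform
#' background. Fold 1 means background (no enrichment) in that condition.
#'
#' @param locus_center window center, bp.
#' @param half_width half-width, bp (> 0).
#' @param fold_by_condition named numeric vector of folds, one per
#'   condition, all finite and >= 1.
#' @param locus_id optional identifier (defaults assigned by
#'   [simulation_config()]).
#' @return An `enrichment_spec` list.
#' @export
enrichment_spec <- function(locus_center, half_width, fold_by_condition,
                            locus_id = NULL) {
  stopifnot(half_width > 0, length(fold_by_condition) >= 1)
  if (is.null(names(fold_by_condition)) ||
      any(!nzchar(names(fold_by_condition)))) {
    stop("fold_by_condition must be a named vector (condition -> fold)")
  }
  if (any(!is.finite(fold_by_condition)) || any(fold_by_condition < 1)) {
    stop("folds must be finite and >= 1")
  }
  structure(
    list(locus_center = as.integer(locus_center),
         half_width = as.integer(half_width),
         fold_by_condition = fold_by_condition,
         locus_id = locus_id),
    class = "enrichment_spec"
  )
}

#' Configure a simulation
#'
#' Bundles the study conditions of the synthetic data: genome size and gene
#' count, sequencing depth per condition, fragment-length range (default
#' 300-500 bp, the shearing target of the emulated protocol), planted
#' enrichment windows, and the seed. The whole simulation output is a pure
#' function of this object.
#'
#' @param genome_length genome length in bp, default 200000.
#' @param n_genes number of genes to place, default 50.
#' @param n_reads_per_condition reads simulated per condition, default 1e5.
#' @param fragment_length_range inclusive `[min, max]` fragment length in
#'   bp, default `c(300, 500)`.
#' @param enrichments list of [enrichment_spec()]s.
#' @param seed integer RNG seed.
#' @param genome_name replicon name, default `"synthetic"`.
#' @param circular simulate a circular chromosome, default `TRUE`.
#' @param gene_length_range inclusive gene length range in bp, default
#'   `c(600, 1500)` (typical bacterial ORFs).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(genome_length = 200000L, n_genes = 50L,
                              n_reads_per_condition = 100000L,
                              fragment_length_range = c(300L, 500L),
                              enrichments = list(), seed = 1L,
                              genome_name = "synthetic", circular = TRUE,
                              gene_length_range = c(600L, 1500L)) {
  stopifnot(genome_length > 0, n_genes >= 0, n_reads_per_condition >= 0,
            length(fragment_length_range) == 2,
            fragment_length_range[1] > 0,
            fragment_length_range[1] <= fragment_length_range[2],
            fragment_length_range[2] <= genome_length)
  enrichments <- lapply(seq_along(enrichments), function(i) {
    e <- enrichments[[i]]
    stopifnot(inherits(e, "enrichment_spec"))
    if (is.null(e$locus_id)) e$locus_id <- sprintf("locus%d", i)
    if (!circular && (e$locus_center - e$half_width < 0 ||
                      e$locus_center + e$half_width > genome_length)) {
      stop("enrichment window of ", e$locus_id,
           " extends outside the linear genome")
    }
    if (e$locus_center < 0 || e$locus_center >= genome_length) {
      stop("locus_center of ", e$locus_id, " outside [0, genome_length)")
    }
    e
  })
  conds <- lapply(enrichments, function(e) sort(names(e$fold_by_condition)))
  if (length(conds) > 1 && !all(vapply(conds, identical, TRUE, conds[[1]]))) {
    stop("all enrichment specs must name the same set of conditions")
  }
  structure(
    list(genome_length = as.integer(genome_length),
         n_genes = as.integer(n_genes),
         n_reads_per_condition = as.integer(n_reads_per_condition),
         fragment_length_range = as.integer(fragment_length_range),
         enrichments = enrichments, seed = as.integer(seed),
         genome_name = genome_name, circular = isTRUE(circular),
         gene_length_range = as.integer(gene_length_range)),
    class = "simulation_config"
  )
}

#' Generate a synthetic genome with gene models
#'
#' Places `n_genes` non-overlapping genes of random length
#' (`gene_length_range`) and random strand uniformly on the genome by
#' rejection sampling. Deterministic under the config seed; placement that
#' fails after bounded retries is a hard error.
#'
#' @param config a [simulation_config()].
#' @return A [genome_model()].
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$genome_length
  n <- config$n_genes
  if (n == 0L) {
    return(genome_model(config$genome_name, L, circular = config$circular))
  }
  if (n * mean(config$gene_length_range) > 0.8 * L) {
    stop("gene placement infeasible: ", n, " genes will not fit ", L, " bp")
  }
  with_seed(config$seed, {
    lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                   n, replace = TRUE)
    starts <- integer(0)
    ends <- integer(0)
    max_tries <- 100L * n
    tries <- 0L
    for (len in lens) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("gene placement failed after ", max_tries, " attempts")
        }
        s <- sample.int(L - len, 1L) - 1L
        e <- s + len
        if (!any(s < ends & e > starts)) {
          starts <- c(starts, s)
          ends <- c(ends, e)
          break
        }
      }
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    genes <- gene_table(sprintf("gene%03d", seq_len(n)), starts, ends,
                        strands)
    genome_model(config$genome_name, L, circular = config$circular,
                 genes = genes)
  })
}

#' Simulate an IP read set for one condition
#'
#' Fragment midpoints are drawn from a mixture of a uniform background over
#' the whole genome and the planted windows, each window's extra mass
#' proportional to `(fold - 1) * width`, so the expected midpoint density
#' inside a window is `fold` times the background. Fragment lengths are
#' uniform on `fragment_length_range`; strands are random; all reads are
#' uniquely mapped. On a circular genome a fragment crossing the origin
#' junction is split into two intervals sharing one `read_id`.
#'
#' @param genome the [genome_model()] the reads map to.
#' @param config a [simulation_config()]; every enrichment must carry a
#'   fold for `condition`.
#' @param condition condition name.
#' @return An [aligned_reads()] tibble with exactly
#'   `n_reads_per_condition` distinct reads.
#' @export
simulate_reads <- function(genome, config, condition) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$genome_length
  n <- config$n_reads_per_condition
  if (n == 0L) {
    return(aligned_reads(character(), integer(), integer(), character()))
  }
  folds <- vapply(config$enrichments, function(e) {
    f <- e$fold_by_condition[condition]
    if (is.na(f)) stop("condition '", condition, "' missing from ",
                       e$locus_id, " fold map")
    unname(f)
  }, numeric(1))
  widths <- vapply(config$enrichments, function(e) 2 * e$half_width,
                   numeric(1))
  centers <- vapply(config$enrichments, function(e) e$locus_center,
                    numeric(1))
  extra <- (folds - 1) * widths
  mass <- c(L, extra)

  with_seed(condition_seed(config$seed, condition), {
    comp <- sample.int(length(mass), n, replace = TRUE, prob = mass)
    mid <- integer(n)
    bg <- comp == 1L
    mid[bg] <- sample.int(L, sum(bg), replace = TRUE) - 1L
    for (i in seq_along(extra)) {
      sel <- comp == i + 1L
      if (any(sel)) {
        offs <- sample.int(widths[i], sum(sel), replace = TRUE) - 1L
        mid[sel] <- (centers[i] - config$enrichments[[i]]$half_width +
                       offs) %% L
      }
    }
    lens <- sample(config$fragment_length_range[1]:
                     config$fragment_length_range[2], n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    start <- mid - lens %/% 2L
    ids <- sprintf("%s_read%06d", condition, seq_len(n))
    if (config$circular) {
      start <- start %% L
      end <- start + lens
      wraps <- end > L
      # junction-split fragments: two intervals, one read id
      s <- c(start[!wraps], start[wraps], rep(0L, sum(wraps)))
      e <- c(end[!wraps], rep(L, sum(wraps)), end[wraps] - L)
      st <- c(strands[!wraps], strands[wraps], strands[wraps])
      id <- c(ids[!wraps], ids[wraps], ids[wraps])
    } else {
      start <- pmax(0L, pmin(start, L - lens))
      s <- start
      e <- start + lens
      st <- strands
      id <- ids
    }
    ord <- order(id, s)
    aligned_reads(reference = genome$name, start = s[ord], end = e[ord],
                  strand = st[ord], unique = TRUE, read_id = id[ord])
  })
}

#' Ground-truth table of planted enrichment
#'
#' One row per (planted locus, condition) with the expected fold; a pure
#' function of the config (no RNG). Loci whose fold is 1 in every
#' condition are flagged `background`.
#'
#' @param config a [simulation_config()].
#' @return Tibble: `locus_id`, `center`, `half_width`, `start`, `end`,
#'   `condition`, `expected_fold`, `background`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- lapply(config$enrichments, function(e) {
    tibble::tibble(
      locus_id = e$locus_id,
      center = e$locus_center,
      half_width = e$half_width,
      start = e$locus_center - e$half_width,
      end = e$locus_center + e$half_width,
      condition = names(e$fold_by_condition),
      expected_fold = unname(e$fold_by_condition),
      background = all(e$fold_by_condition == 1)
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(locus_id = character(), center = integer(),
                          half_width = integer(), start = integer(),
                          end = integer(), condition = character(),
                          expected_fold = numeric(), background = logical()))
  }
  dplyr::bind_rows(rows)
}

## Strand-aware anchor for planting a promoter-proximal peak: 200 bp
## upstream of the TSS, inside the -500/+100 annotation window.
promoter_anchor <- function(gene) {
  if (gene$strand == "+") gene$tss - 200L else gene$tss + 200L
}

#' Build the two-condition demo simulation
#'
#' The package's reference synthetic dataset: a 200 kb circular genome with
#' 50 genes and two conditions (`WT`, `mutant`) sequenced at `n_reads`
#' reads each, with three planted windows of half-width 1500 bp at fold 10
#' — an origin-like locus in the largest intergenic gap (enriched in both
#' conditions), a promoter-proximal locus enriched in both, and a
#' promoter-proximal locus enriched only in the mutant (fold 10 vs 1), the
#' planted differential target. The default half-width keeps the truth
#' window wide relative to the fragment-length resolution limit
#' (coverage smears ~(fragment length)/2 beyond the region of enriched
#' midpoints), emulating a clustered-binding-site region rather than a
#' single footprint.
#'
#' @param seed integer RNG seed.
#' @param n_reads reads per condition, default 1e5.
#' @param genome_length genome length, default 200000.
#' @param n_genes gene count, default 50.
#' @param half_width planted window half-width, default 2000.
#' @return List: `config` (with enrichments filled in), `genome`, and
#'   `diff_gene_id`, the gene whose promoter carries the differential
#'   locus.
#' @export
demo_simulation <- function(seed = 1L, n_reads = 100000L,
                            genome_length = 200000L, n_genes = 50L,
                            half_width = 2000L) {
  base <- simulation_config(
    genome_length = genome_length, n_genes = n_genes,
    n_reads_per_condition = n_reads, seed = seed
  )
  genome <- make_genome(base)
  genes <- genome$genes
  L <- genome$length

  # origin-like locus: middle of the largest intergenic gap
  gaps_start <- c(0L, genes$end)
  gaps_end <- c(genes$start, L)
  widest <- which.max(gaps_end - gaps_start)
  ori_center <- as.integer((gaps_start[widest] + gaps_end[widest]) %/% 2)

  # two promoter-proximal loci on well-separated genes, away from the
  # origin-like window
  anchor <- vapply(seq_len(nrow(genes)), function(i) {
    promoter_anchor(genes[i, ]) %% L
  }, integer(1))
  circ_dist <- function(a, b) pmin(abs(a - b), L - abs(a - b))
  ok <- circ_dist(anchor, ori_center) > 4L * half_width
  pick <- function(target, exclude) {
    cand <- which(ok & !(seq_along(anchor) %in% exclude))
    cand[which.min(abs(anchor[cand] - target))]
  }
  g_shared <- pick(round(L / 3), integer(0))
  g_diff <- pick(round(2 * L / 3), g_shared)

  enr <- list(
    enrichment_spec(ori_center, half_width,
                    c(WT = 10, mutant = 10), locus_id = "ori_like"),
    enrichment_spec(anchor[g_shared], half_width,
                    c(WT = 10, mutant = 10), locus_id = "prom_shared"),
    enrichment_spec(anchor[g_diff], half_width,
                    c(WT = 1, mutant = 10), locus_id = "prom_diff")
  )
  config <- simulation_config(
    genome_length = genome_length, n_genes = n_genes,
    n_reads_per_condition = n_reads, enrichments = enr, seed = seed
  )
  list(config = config, genome = genome,
       diff_gene_id = genes$gene_id[g_diff])
}
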