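#' Compute the peak-calling cutoff for one sample
#'
#' The cutoff separating candidate peaks from background noise is the mean
#' of all probe percent values plus `multiplier` (default 2) times their
#' standard deviation, computed per sample over the full probe track. The
#' SD uses the n-1 (sample) denominator; at genome scale (~80k probes) the
#' choice of denominator is numerically irrelevant.
#'
#' @param track a [probe_track()] with at least 2 probes.
#' @param multiplier number of standard deviations above the mean,
#'   default 2.
#' @return A list with `mean`, `sd` and `cutoff = mean + multiplier * sd`,
#'   all in percent units.
#' @export
compute_cutoff <- function(track, multiplier = 2) {
  x <- track$probes$percent
  if (length(x) < 2L) stop("cutoff needs at least 2 probes")
  m <- mean(x)
  s <- stats::sd(x)
  list(mean = m, sd = s, cutoff = m + multiplier * s)
}

#' Select candidate probes above a cutoff
#'
#' A probe is a candidate when its percent value is strictly greater than
#' the cutoff; ties at the cutoff are background.
#'
#' @param track a [probe_track()].
#' @param cutoff finite cutoff in percent units.
#' @return Sorted integer indices into the probe grid.
#' @export
call_candidates <- function(track, cutoff) {
  stopifnot(is.finite(cutoff))
  which(track$probes$percent > cutoff)
}

#' Merge consecutive candidate probes into peaks
#'
#' Maximal runs of consecutive candidate indices become single peak
#' intervals; an isolated candidate is a single-probe peak.
#'
#' @param candidates sorted candidate probe indices.
#' @param probes the probe grid the indices refer to.
#' @return Tibble of peak intervals: `start`, `end`, `n_probes`.
#' @export
merge_candidates <- function(candidates, probes) {
  if (length(candidates) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_probes = integer()))
  }
  candidates <- as.integer(candidates)
  run <- cumsum(c(1L, diff(candidates) != 1L))
  first <- candidates[!duplicated(run)]
  last <- candidates[rev(!duplicated(rev(run)))]
  tibble::tibble(start = probes$start[first],
                 end = probes$end[last],
                 n_probes = as.integer(tabulate(run)))
}

#' Call peaks on a probe track
#'
#' Runs the full per-sample peak call: cutoff at mean plus `multiplier`
#' standard deviations of the percent values, strict thresholding, and
#' merging of consecutive supra-threshold probes. Each merged peak carries
#' the maximum percent among its probes.
#'
#' @param track a [probe_track()].
#' @param multiplier SD multiplier for the cutoff, default 2.
#' @return A `peak_call` object: `mean`, `sd`, `cutoff`, `candidates`
#'   (probe indices) and `peaks` (merged intervals with `max_percent`).
#' @export
call_peaks <- function(track, multiplier = 2) {
  stats <- compute_cutoff(track, multiplier)
  candidates <- call_candidates(track, stats$cutoff)
  peaks <- merge_candidates(candidates, track$probes)
  if (nrow(peaks) > 0) {
    run <- cumsum(c(1L, diff(candidates) != 1L))
    peaks$max_percent <- as.numeric(tapply(
      track$probes$percent[candidates], factor(run, levels = unique(run)),
      max))
  } else {
    peaks$max_percent <- numeric()
  }
  structure(
    list(genome_name = track$genome_name, mean = stats$mean, sd = stats$sd,
         cutoff = stats$cutoff, candidates = candidates, peaks = peaks),
    class = "peak_call"
  )
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf(
    "<peak_call> %s: cutoff %.4g%% (mean %.4g + sd), %d candidate probes, %d peaks\n",
    x$genome_name, x$cutoff, x$mean, length(x$candidates), nrow(x$peaks)))
  invisible(x)
}

#' Write called peaks as BED6
#'
#' Score column carries the peak's maximum probe percent.
#'
#' @param peak_call a [call_peaks()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peak_call, path) {
  p <- peak_call$peaks
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                   peak_call$genome_name, p$start, p$end,
                   sprintf("peak%d", seq_len(nrow(p))),
                   sprintf("%.6g", p$max_percent))
  writeLines(lines, path)
  invisible(path)
}
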