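# Replicate consensus: a peak is kept per condition when it is detected in
# both replicates (merged with max-breadth / max-density rules) or when a
# singleton has fold enrichment above the rescue threshold.

validate_peaks <- function(peaks, what = "peaks") {
  need <- c("chrom", "start", "end", "fold_enrichment")
  if (!all(need %in% names(peaks)))
    abort_arg(what, " must have columns ", paste(need, collapse = ", "))
  if (nrow(peaks) && any(peaks$start >= peaks$end))
    abort_arg(what, ": malformed coordinates (start >= end)")
  if (nrow(peaks) && any(peaks$fold_enrichment <= 0))
    abort_arg(what, ": fold_enrichment must be > 0")
  invisible(peaks)
}

peaks_granges <- function(peaks, seqlevels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(factor(peaks$chrom, levels = seqlevels),
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Pair replicate peaks by maximum overlap
#'
#' Forms one-to-one pairs between two replicate peak lists: candidate pairs
#' are peaks on the same chromosome overlapping by at least one base; pairs
#' are chosen greedily by decreasing overlap width, ties broken by leftmost
#' replicate-1 start then leftmost replicate-2 start. Each peak joins at most
#' one pair.
#'
#' @param rep1,rep2 Peak data frames (0-based half-open `start`/`end`).
#' @return List with `pairs` (two-column matrix of row indices into
#'   `rep1`/`rep2`), `leftover1`, `leftover2` (unpaired row indices).
#' @export
pair_replicate_peaks <- function(rep1, rep2) {
  validate_peaks(rep1, "rep1"); validate_peaks(rep2, "rep2")
  if (nrow(rep1) == 0L || nrow(rep2) == 0L)
    return(list(pairs = cbind(i1 = integer(0), i2 = integer(0)),
                leftover1 = seq_len(nrow(rep1)),
                leftover2 = seq_len(nrow(rep2))))
  lv <- unique(c(rep1$chrom, rep2$chrom))
  hits <- GenomicRanges::findOverlaps(peaks_granges(rep1, lv),
                                      peaks_granges(rep2, lv))
  i1 <- S4Vectors::queryHits(hits); i2 <- S4Vectors::subjectHits(hits)
  ov <- pmin(rep1$end[i1], rep2$end[i2]) - pmax(rep1$start[i1], rep2$start[i2])
  ord <- order(-ov, rep1$start[i1], rep2$start[i2])
  used1 <- logical(nrow(rep1)); used2 <- logical(nrow(rep2))
  p1 <- integer(0); p2 <- integer(0)
  for (k in ord) {
    if (used1[i1[k]] || used2[i2[k]]) next
    used1[i1[k]] <- TRUE; used2[i2[k]] <- TRUE
    p1 <- c(p1, i1[k]); p2 <- c(p2, i2[k])
  }
  list(pairs = cbind(i1 = p1, i2 = p2),
       leftover1 = which(!used1), leftover2 = which(!used2))
}

#' Merge one replicate peak pair into a consensus peak
#'
#' The coordinates of the replicate peak with the larger breadth are taken
#' (ties: larger tag density, then replicate 1); tag density is the maximum
#' of the two, as is fold enrichment.
#'
#' @param p1,p2 Single-row peak data frames that overlap on one chromosome.
#' @return Single-row consensus peak data frame with a `support` column.
#' @export
merge_replicate_peak <- function(p1, p2) {
  if (p1$chrom != p2$chrom || p1$start >= p2$end || p2$start >= p1$end)
    stop("merge_replicate_peak: peaks do not overlap")
  b1 <- p1$end - p1$start; b2 <- p2$end - p2$start
  take1 <- b1 > b2 || (b1 == b2 && p1$tag_density >= p2$tag_density)
  out <- if (take1) p1 else p2
  out$breadth <- out$end - out$start
  out$tag_density <- max(p1$tag_density, p2$tag_density)
  out$fold_enrichment <- max(p1$fold_enrichment, p2$fold_enrichment)
  out$support <- "both_replicates"
  out
}

#' Build the summarized (consensus) peak list for one condition
#'
#' Pairs the two replicates with [pair_replicate_peaks()], merges each pair
#' with [merge_replicate_peak()], and rescues unpaired peaks whose fold
#' enrichment is strictly above `fe_threshold` (default 5.0); all other
#' singletons are discarded.
#'
#' @param rep1,rep2 Replicate peak data frames.
#' @param fe_threshold High-reliability rescue threshold (strict `>`).
#' @param rescue If `FALSE`, the rescue rule is disabled and only
#'   both-replicate peaks are kept.
#' @return Consensus peak data frame sorted by (chrom, start), with a
#'   `support` column in `{both_replicates, rescue_fe}`.
#' @export
build_summary_peaks <- function(rep1, rep2, fe_threshold = 5.0, rescue = TRUE) {
  if (fe_threshold <= 0) abort_arg("fe_threshold must be > 0")
  m <- pair_replicate_peaks(rep1, rep2)
  merged <- if (nrow(m$pairs)) {
    do.call(rbind, lapply(seq_len(nrow(m$pairs)), function(k)
      merge_replicate_peak(rep1[m$pairs[k, 1], , drop = FALSE],
                           rep2[m$pairs[k, 2], , drop = FALSE])))
  }
  singletons <- rbind(rep1[m$leftover1, , drop = FALSE],
                      rep2[m$leftover2, , drop = FALSE])
  rescued <- if (rescue && nrow(singletons)) {
    keep <- singletons[singletons$fold_enrichment > fe_threshold, , drop = FALSE]
    if (nrow(keep)) { keep$support <- "rescue_fe"; keep$breadth <- keep$end - keep$start }
    keep
  }
  out <- rbind(merged, if (!is.null(rescued) && nrow(rescued)) rescued)
  if (is.null(out) || nrow(out) == 0L) {
    out <- rep1[integer(0), , drop = FALSE]
    out$support <- character(0)
    return(out)
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}
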