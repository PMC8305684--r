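# RNA-seq integration: RPM/RPKM normalization, log expression differences
# between sample groups, pooled Welch tests of cluster expression, gene-set
# Z-scores and hypergeometric over-representation.

#' Reads-per-million normalization
#'
#' @param counts Nonnegative gene x sample count matrix.
#' @return Matrix of the same shape; every column sums to 1e6.
#' @export
rpm <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot <= 0)) abort_arg("zero-total sample column")
  sweep(counts, 2, tot, "/") * 1e6
}

#' RPKM from an RPM matrix and gene lengths
#'
#' @param rpm_matrix RPM matrix from [rpm()].
#' @param lengths Named vector of gene lengths in bases covering all rows.
#' @return RPKM matrix (`rpm * 1000 / length`).
#' @export
rpkm <- function(rpm_matrix, lengths) {
  len <- lengths[rownames(rpm_matrix)]
  if (anyNA(len)) abort_arg("missing gene lengths")
  if (any(len <= 0)) abort_arg("lengths must be positive")
  rpm_matrix * 1000 / as.numeric(len)
}

#' Log10 expression difference of one gene between two sample groups
#'
#' `log10(mean RPKM in group_b + pseudocount) - log10(mean RPKM in group_a
#' + pseudocount)`; positive values mean activation in group B.
#'
#' @param rpkm_matrix RPKM matrix.
#' @param gene Gene id (row).
#' @param group_a,group_b Sample id vectors.
#' @param pseudocount Added inside the log (default 0.1 RPKM).
#' @return Numeric scalar.
#' @export
delta_log_T <- function(rpkm_matrix, gene, group_a, group_b,
                        pseudocount = 0.1) {
  if (!length(group_a) || !length(group_b)) abort_arg("empty group")
  a <- mean(rpkm_matrix[gene, group_a])
  b <- mean(rpkm_matrix[gene, group_b])
  log10(b + pseudocount) - log10(a + pseudocount)
}

#' Welch test of a cluster's expression between two sample groups
#'
#' Pools one observation per gene per group — the gene's mean
#' log10(RPKM + pseudocount) over the group's samples — and applies a
#' two-sided Welch two-sample t-test (group B minus group A, so a positive
#' statistic means activation in B). Degenerate (constant) data is flagged
#' rather than crashing.
#'
#' @param rpkm_matrix RPKM matrix.
#' @param cluster_genes Gene ids of the cluster (>= 2).
#' @param group_a,group_b Sample id vectors.
#' @param pseudocount Log offset.
#' @return List: `statistic`, `p.value`, `df`, `degenerate`.
#' @export
cluster_expression_test <- function(rpkm_matrix, cluster_genes, group_a,
                                    group_b, pseudocount = 0.1) {
  g <- intersect(cluster_genes, rownames(rpkm_matrix))
  if (length(g) < 2L) abort_arg("need >= 2 cluster genes in the matrix")
  la <- log10(rpkm_matrix[g, group_a, drop = FALSE] + pseudocount)
  lb <- log10(rpkm_matrix[g, group_b, drop = FALSE] + pseudocount)
  xa <- rowMeans(la); xb <- rowMeans(lb)
  res <- tryCatch(t.test(xb, xa, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res))
    return(list(statistic = 0, p.value = NA_real_, df = NA_real_,
                degenerate = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       df = unname(res$parameter), degenerate = FALSE)
}

#' Gene-set Z-scores per sample
#'
#' Each gene's log10(RPKM + pseudocount) is centered and scaled across
#' samples; the set score in a sample is the mean of the member genes'
#' z-scores times `sqrt(set size)` — a standardized mean, so coherent
#' up-shifts of the set in a sample give large positive scores and the
#' score grows with the square root of the set size. Genes with zero
#' variance across samples contribute z = 0; missing ids are reported and
#' skipped.
#'
#' @param rpkm_matrix RPKM matrix.
#' @param gene_ids Gene set members.
#' @param pseudocount Log offset.
#' @return Named numeric vector of scores, one per sample.
#' @export
gsz_score <- function(rpkm_matrix, gene_ids, pseudocount = 0.1) {
  present <- intersect(gene_ids, rownames(rpkm_matrix))
  if (!length(present)) abort_arg("gene set fully absent from the matrix")
  if (length(present) < length(gene_ids))
    warning(length(gene_ids) - length(present), " gene(s) not in matrix; skipped")
  lx <- log10(rpkm_matrix[present, , drop = FALSE] + pseudocount)
  mu <- rowMeans(lx)
  sdv <- apply(lx, 1, sd)
  z <- (lx - mu) / ifelse(sdv > 0, sdv, Inf)
  colMeans(z) * sqrt(length(present))
}

#' Hypergeometric over-representation of gene sets in a cluster
#'
#' One-sided upper-tail hypergeometric p-value for the overlap of a cluster
#' with each gene set inside a universe, with fold enrichment
#' (observed / expected overlap) and Benjamini-Hochberg correction across
#' sets. A zero expected overlap yields `NA` fold.
#'
#' @param cluster_genes Gene ids of the cluster (must lie in `universe`).
#' @param sets Named list of gene-id vectors.
#' @param universe Character vector of all considered gene ids.
#' @return Data frame: `set`, `set_size`, `overlap`, `expected`, `fold`,
#'   `p`, `p_adj`.
#' @export
enrichment_test <- function(cluster_genes, sets, universe) {
  if (!length(universe)) abort_arg("empty universe")
  universe <- unique(universe)
  cluster_genes <- intersect(unique(cluster_genes), universe)
  if (length(setdiff(cluster_genes, universe)))
    abort_arg("cluster genes outside the universe")
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(cluster_genes, set))
    K <- length(set); n <- length(cluster_genes); N <- length(universe)
    expected <- n * K / N
    data.frame(set = nm, set_size = K, overlap = k, expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Reliable-expression gene filter
#'
#' Genes measured with sufficient reliability: mean RPKM at or above
#' `min_mean_rpkm` across all samples.
#'
#' @param rpkm_matrix RPKM matrix.
#' @param min_mean_rpkm Threshold (default 1).
#' @return Character vector of passing gene ids.
#' @export
reliable_genes <- function(rpkm_matrix, min_mean_rpkm = 1) {
  rownames(rpkm_matrix)[rowMeans(rpkm_matrix) >= min_mean_rpkm]
}
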