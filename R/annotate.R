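# Per-gene binary modification coding: a gene carries a mark in a sample iff
# some consensus peak overlaps its promoter (TSS +/- flank) and/or gene body
# by at least `min_overlap_frac` of the peak's breadth. Codes are two-bit
# strings in mark order H3K4me3 then H3K27me3; sex-chromosome genes and
# peaks are excluded.

#' Promoter region of a gene
#'
#' TSS +/- `flank` bases, strand-aware (TSS is `start` on `+`, `end` on `-`),
#' clipped at the chromosome origin. 0-based half-open.
#'
#' @param gene One-or-more-row gene data frame.
#' @param flank Bases either side of the TSS (default 1000).
#' @return Data frame `chrom`, `start`, `end`.
#' @export
promoter_region <- function(gene, flank = 1000) {
  if (flank < 0) abort_arg("flank must be >= 0")
  tss <- ifelse(gene$strand == "+", gene$start, gene$end)
  data.frame(chrom = gene$chrom, start = pmax(0, tss - flank),
             end = tss + flank, stringsAsFactors = FALSE)
}

#' Gene body region
#'
#' The region between the TSS and the last base of the gene; with half-open
#' coordinates this is simply `[start, end)` irrespective of strand.
#'
#' @param gene Gene data frame.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
gene_body_region <- function(gene) {
  data.frame(chrom = gene$chrom, start = gene$start, end = gene$end,
             stringsAsFactors = FALSE)
}

# Union of promoter and body is a single contiguous interval for flank >= 0:
# the promoter always touches the body at the TSS.
gene_region_union <- function(genes, flank = 1000) {
  prom <- promoter_region(genes, flank)
  body <- gene_body_region(genes)
  data.frame(chrom = genes$chrom,
             start = pmin(prom$start, body$start),
             end = pmax(prom$end, body$end), stringsAsFactors = FALSE)
}

#' Binary modification call for one gene
#'
#' Returns 1 iff any peak overlaps the union of the gene's promoter and body
#' by at least `min_overlap_frac`, measured as a fraction of the peak's
#' breadth (`mode = "peak"`, the default) or of the gene region's width
#' (`mode = "region"`). The boundary is inclusive (>=), and presence is
#' binary — no dosage.
#'
#' @param gene Single-row gene data frame.
#' @param peaks Peak data frame, all of one mark.
#' @param min_overlap_frac Minimum overlap fraction in (0, 1].
#' @param flank Promoter flank in bases.
#' @param mode Denominator of the overlap fraction.
#' @return `0L` or `1L`.
#' @export
assign_modification <- function(gene, peaks, min_overlap_frac = 0.05,
                                flank = 1000, mode = c("peak", "region")) {
  mode <- match.arg(mode)
  if (min_overlap_frac <= 0 || min_overlap_frac > 1)
    abort_arg("min_overlap_frac must be in (0, 1]")
  if (nrow(peaks) == 0L) return(0L)
  reg <- gene_region_union(gene, flank)
  same <- peaks$chrom == reg$chrom
  ov <- pmax(0, pmin(peaks$end, reg$end) - pmax(peaks$start, reg$start))
  denom <- switch(mode, peak = peaks$end - peaks$start,
                  region = rep(reg$end - reg$start, nrow(peaks)))
  frac <- ifelse(same, ov / denom, 0)
  as.integer(any(frac >= min_overlap_frac))
}

# Vectorized modification bits for all genes against one peak list.
assign_modification_all <- function(genes, peaks, min_overlap_frac = 0.05,
                                    flank = 1000, mode = "peak") {
  bits <- integer(nrow(genes))
  if (nrow(peaks) == 0L) return(bits)
  reg <- gene_region_union(genes, flank)
  lv <- unique(c(reg$chrom, peaks$chrom))
  gr <- GenomicRanges::GRanges(factor(reg$chrom, levels = lv),
                               IRanges::IRanges(reg$start + 1L, reg$end))
  pr <- peaks_granges(peaks, lv)
  hits <- GenomicRanges::findOverlaps(pr, gr)
  ip <- S4Vectors::queryHits(hits); ig <- S4Vectors::subjectHits(hits)
  ov <- pmin(peaks$end[ip], reg$end[ig]) - pmax(peaks$start[ip], reg$start[ig])
  denom <- if (mode == "peak") peaks$end[ip] - peaks$start[ip]
           else reg$end[ig] - reg$start[ig]
  pass <- ov / denom >= min_overlap_frac
  bits[unique(ig[pass])] <- 1L
  bits
}

#' Build the gene x sample modification code matrix
#'
#' Genes (and peaks) on chrX/chrY are excluded, then each cell receives the
#' two-bit code `<K4><K27>` from [assign_modification()] over the sample's
#' consensus peak lists.
#'
#' @param genes Gene reference data frame.
#' @param consensus Nested list: `consensus[[sample]][[mark]]` is a consensus
#'   peak data frame; every sample must provide both `H3K4me3` and
#'   `H3K27me3`.
#' @param min_overlap_frac,flank,mode Passed to the overlap rule.
#' @return Character matrix (class `code_matrix`) of codes in
#'   `{"00","10","01","11"}`, rownames gene ids, colnames sample ids.
#' @export
build_code_matrix <- function(genes, consensus, min_overlap_frac = 0.05,
                              flank = 1000, mode = "peak") {
  keep <- !is_sex_chrom(genes$chrom)
  genes <- genes[keep, , drop = FALSE]
  codes <- matrix("", nrow(genes), length(consensus),
                  dimnames = list(genes$gene_id, names(consensus)))
  for (s in names(consensus)) {
    pk <- consensus[[s]]
    if (!all(c("H3K4me3", "H3K27me3") %in% names(pk)))
      abort_arg("sample ", s, " must provide both H3K4me3 and H3K27me3 peaks")
    k4 <- assign_modification_all(genes, drop_sex_peaks(pk$H3K4me3),
                                  min_overlap_frac, flank, mode)
    k27 <- assign_modification_all(genes, drop_sex_peaks(pk$H3K27me3),
                                   min_overlap_frac, flank, mode)
    codes[, s] <- paste0(k4, k27)
  }
  structure(codes, class = c("code_matrix", class(codes)))
}

drop_sex_peaks <- function(peaks) peaks[!is_sex_chrom(peaks$chrom), , drop = FALSE]

#' Per-sample distribution of the four modification states
#'
#' @param codes A `code_matrix`.
#' @return 4 x sample numeric matrix of fractions (rows `00`,`10`,`01`,`11`),
#'   each column summing to 1.
#' @export
state_frequencies <- function(codes) {
  if (nrow(codes) == 0L) abort_arg("empty code matrix")
  out <- vapply(seq_len(ncol(codes)), function(j) {
    tab <- table(factor(codes[, j], levels = MOD_STATES))
    as.numeric(tab) / nrow(codes)
  }, numeric(4))
  dimnames(out) <- list(MOD_STATES, colnames(codes))
  out
}

#' Per-sample counts of total and gene-associated quality peaks
#'
#' A peak is gene-associated iff the overlap rule would count it for at
#' least one (non-sex-chromosome) gene. Sex-chromosome peaks are excluded
#' from both counts.
#'
#' @param genes Gene reference data frame.
#' @param consensus Nested list as in [build_code_matrix()].
#' @inheritParams build_code_matrix
#' @return Data frame with columns `sample`, `mark`, `total`,
#'   `gene_associated`.
#' @export
peak_summary <- function(genes, consensus, min_overlap_frac = 0.05,
                         flank = 1000, mode = "peak") {
  genes <- genes[!is_sex_chrom(genes$chrom), , drop = FALSE]
  reg <- gene_region_union(genes, flank)
  rows <- list()
  for (s in names(consensus)) for (mk in names(consensus[[s]])) {
    pk <- drop_sex_peaks(consensus[[s]][[mk]])
    assoc <- 0L
    if (nrow(pk)) {
      lv <- unique(c(reg$chrom, pk$chrom))
      gr <- GenomicRanges::GRanges(factor(reg$chrom, levels = lv),
                                   IRanges::IRanges(reg$start + 1L, reg$end))
      pr <- peaks_granges(pk, lv)
      hits <- GenomicRanges::findOverlaps(pr, gr)
      ip <- S4Vectors::queryHits(hits); ig <- S4Vectors::subjectHits(hits)
      ov <- pmin(pk$end[ip], reg$end[ig]) - pmax(pk$start[ip], reg$start[ig])
      denom <- if (mode == "peak") pk$end[ip] - pk$start[ip]
               else reg$end[ig] - reg$start[ig]
      assoc <- length(unique(ip[ov / denom >= min_overlap_frac]))
    }
    rows[[length(rows) + 1L]] <- data.frame(sample = s, mark = mk,
                                            total = nrow(pk),
                                            gene_associated = assoc)
  }
  do.call(rbind, rows)
}
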