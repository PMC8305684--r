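# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use per-base / per-step mechanics, never the package's interval code.

make_peak <- function(chrom, start, end, fe = 10, density = 10,
                      mark = "H3K4me3", sample_id = "s_r1") {
  n <- length(chrom)
  data.frame(chrom = chrom, start = start, end = end, breadth = end - start,
             fold_enrichment = rep_len(fe, n), tag_density = rep_len(density, n),
             mark = rep_len(mark, n), sample_id = rep_len(sample_id, n),
             stringsAsFactors = FALSE)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 5000) {
  if (n == 0L) return(make_peak(character(0), integer(0), integer(0))[0, ])
  s <- sample.int(span, n, replace = TRUE)
  w <- sample(20:400, n, replace = TRUE)
  make_peak(sample(chroms, n, replace = TRUE), s, s + w,
            fe = round(runif(n, 0.5, 12), 2),
            density = round(runif(n, 1, 30), 2))
}

# Brute-force consensus oracle: repeatedly scan all unused cross-replicate
# pairs, counting shared bases one interval at a time; take the pair with
# the most shared bases (ties: leftmost rep1 start, then rep2 start), then
# apply the merge and rescue rules literally.
oracle_consensus <- function(rep1, rep2, fe_threshold = 5, rescue = TRUE) {
  used1 <- logical(nrow(rep1)); used2 <- logical(nrow(rep2))
  rows <- list()
  shared_bases <- function(p, q) {
    if (p$chrom != q$chrom) return(0L)
    length(intersect(seq(p$start, p$end - 1), seq(q$start, q$end - 1)))
  }
  repeat {
    best <- NULL
    for (i in which(!used1)) for (j in which(!used2)) {
      ov <- shared_bases(rep1[i, ], rep2[j, ])
      if (ov < 1) next
      cand <- c(ov, rep1$start[i], rep2$start[j], i, j)
      if (is.null(best) || cand[1] > best[1] ||
          (cand[1] == best[1] && (cand[2] < best[2] ||
           (cand[2] == best[2] && cand[3] < best[3]))))
        best <- cand
    }
    if (is.null(best)) break
    i <- best[4]; j <- best[5]
    used1[i] <- TRUE; used2[j] <- TRUE
    p <- rep1[i, ]; q <- rep2[j, ]
    bp <- p$end - p$start; bq <- q$end - q$start
    take <- if (bp > bq) p else if (bq > bp) q else
      if (p$tag_density >= q$tag_density) p else q
    take$tag_density <- max(p$tag_density, q$tag_density)
    take$fold_enrichment <- max(p$fold_enrichment, q$fold_enrichment)
    take$breadth <- take$end - take$start
    take$support <- "both_replicates"
    rows[[length(rows) + 1L]] <- take
  }
  if (rescue) {
    for (i in which(!used1)) if (rep1$fold_enrichment[i] > fe_threshold) {
      r <- rep1[i, ]; r$support <- "rescue_fe"; r$breadth <- r$end - r$start
      rows[[length(rows) + 1L]] <- r
    }
    for (j in which(!used2)) if (rep2$fold_enrichment[j] > fe_threshold) {
      r <- rep2[j, ]; r$support <- "rescue_fe"; r$breadth <- r$end - r$start
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), ]
}

# Per-base overlap oracle for the modification call.
oracle_assign <- function(gene, peaks, min_overlap_frac = 0.05, flank = 1000,
                          mode = "peak") {
  tss <- if (gene$strand == "+") gene$start else gene$end
  region <- union(seq(max(0, tss - flank), tss + flank - 1),
                  seq(gene$start, gene$end - 1))
  for (k in seq_len(nrow(peaks))) {
    if (peaks$chrom[k] != gene$chrom) next
    pb <- seq(peaks$start[k], peaks$end[k] - 1)
    ov <- length(intersect(pb, region))
    denom <- if (mode == "peak") length(pb) else length(region)
    if (ov / denom >= min_overlap_frac) return(1L)
  }
  0L
}

canon_peaks <- function(p) {
  if (is.null(p) || nrow(p) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), support = character(0)))
  out <- p[order(p$chrom, p$start, p$end, p$support),
           c("chrom", "start", "end", "breadth", "fold_enrichment",
             "tag_density", "support")]
  rownames(out) <- NULL
  out
}

small_scenario <- function(n_genes = 400, cluster_sizes = c(a = 20, b = 15,
                             c = 25, d = 15, e = 20, f = 15, g = 15, h = 20),
                           seed = 11) {
  genes <- generate_genome(n_genes, n_autosomes = 4, seed = seed)
  truth <- plant_scenario(genes, cluster_sizes = cluster_sizes, seed = seed)
  list(genes = genes, truth = truth)
}
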