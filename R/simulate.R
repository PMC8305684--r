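# Synthetic-data generator: gene references, planted modification states per
# condition, replicate peak calls with noise, and state-coupled RNA counts.
# This is a stated world with planted ground truth, used to exercise every
# downstream stage without external data.

#' Default condition layout for a drift scenario
#'
#' Three tissue samples plus short-term and long-term organoid cultures from
#' wild-type and mutant animals, mirroring the tissue / 3-week / 20-week
#' design the transition rules expect. Names are condition identifiers,
#' values their condition class.
#'
#' @return Named character vector mapping condition id to one of
#'   `"tissue"`, `"short_term"`, `"long_term"`.
#' @export
default_conditions <- function() {
  c(tissue_1 = "tissue", tissue_2 = "tissue", tissue_3 = "tissue",
    organoid_S_wt = "short_term", organoid_S_mut = "short_term",
    organoid_L_wt = "long_term", organoid_L_mut = "long_term")
}

#' Cluster sizes reported for the real drift clusters
#'
#' Sizes of the eight published clusters: constant active (a), constant
#' repressed (b), the tissue-to-organoid transitions (c--f) and the
#' long-term-only activations (g, h).
#'
#' @return Named integer vector of cluster sizes.
#' @export
reference_cluster_sizes <- function() {
  c(a = 11627L, b = 502L, c = 401L, d = 102L, e = 342L,
    f = 147L, g = 86L, h = 233L)
}

#' Generate a synthetic gene reference
#'
#' Lays out non-overlapping genes along autosomes (and optionally chrX/chrY),
#' with generous intergenic gaps so that a promoter-centred peak can never
#' spill into a neighbouring gene.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_autosomes Number of autosomes, named `chr1..chrN` (>= 1).
#' @param include_sex_chroms If `TRUE`, a fraction of genes is placed on
#'   chrX/chrY (these are excluded later by the coding stage).
#' @param sex_fraction Expected fraction of genes on sex chromosomes.
#' @param gene_length_range Uniform range of gene lengths in bases.
#' @param gap_range Uniform range of intergenic gaps in bases.
#' @param seed Integer seed; output is deterministic per seed.
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `length` (0-based half-open coordinates).
#' @export
generate_genome <- function(n_genes, n_autosomes = 5L, include_sex_chroms = FALSE,
                            sex_fraction = 0.1,
                            gene_length_range = c(2000, 20000),
                            gap_range = c(10000, 30000), seed = 1L) {
  if (n_genes < 1L) abort_arg("n_genes must be >= 1")
  if (n_autosomes < 1L) abort_arg("n_autosomes must be >= 1")
  with_seed(substream_seed(seed, "genome"), {
    chroms <- paste0("chr", seq_len(n_autosomes))
    assign_chrom <- sample(chroms, n_genes, replace = TRUE)
    if (include_sex_chroms) {
      sex <- runif(n_genes) < sex_fraction
      assign_chrom[sex] <- sample(c("chrX", "chrY"), sum(sex), replace = TRUE)
    }
    len <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
    gap <- round(runif(n_genes, gap_range[1], gap_range[2]))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    ord <- order(assign_chrom, seq_len(n_genes))
    start <- numeric(n_genes)
    cursor <- list()
    for (i in ord) {
      ch <- assign_chrom[i]
      at <- if (is.null(cursor[[ch]])) 0 else cursor[[ch]]
      start[i] <- at + gap[i]
      cursor[[ch]] <- start[i] + len[i]
    }
    data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      chrom = assign_chrom, strand = strand,
      start = start, end = start + len, length = len,
      stringsAsFactors = FALSE)
  })
}

# State each cluster label requires in each condition class.
cluster_state <- function(label, condition_class) {
  organoid <- condition_class %in% c("short_term", "long_term")
  longterm <- condition_class == "long_term"
  switch(label,
    a = rep("10", length(condition_class)),
    b = rep("01", length(condition_class)),
    c = ifelse(organoid, "00", "10"),
    d = ifelse(organoid, "01", "00"),
    e = ifelse(organoid, "01", "11"),
    f = ifelse(organoid, "10", "11"),
    g = ifelse(longterm, "10", "11"),
    h = ifelse(longterm, "10", "00"),
    abort_arg("unknown cluster label: ", label))
}

#' Plant a drift scenario over a gene reference
#'
#' Assigns each gene a per-condition modification state. Genes drawn into a
#' named cluster get that cluster's canonical state trajectory (e.g. cluster
#' c: (10) in every tissue condition, (00) in every organoid condition;
#' cluster g: (11) in tissue and short-term, (10) in long-term only).
#' Remaining genes get states drawn at random per condition, rejection-sampled
#' so that no unlabelled gene accidentally realises one of the eight cluster
#' patterns — planted labels are therefore exactly the rule matches.
#'
#' Expression means are coupled to state: high for (10), intermediate for
#' (11), low for (01) and (00).
#'
#' @param genes Gene reference from [generate_genome()].
#' @param conditions Named character vector, condition id -> condition class
#'   (`tissue`, `short_term`, `long_term`).
#' @param cluster_sizes Named vector of counts for labels a--h; may be empty.
#' @param seed Integer seed.
#' @param expr_state_mean Named vector mapping state to mean expression
#'   (arbitrary units; only ratios matter downstream).
#' @return Object of class `planted_truth`: list with `gene_id`,
#'   `cluster_label`, `states` (gene x condition character matrix),
#'   `expr` (gene x condition numeric matrix) and `conditions`.
#' @export
plant_scenario <- function(genes, conditions = default_conditions(),
                           cluster_sizes = NULL, seed = 1L,
                           expr_state_mean = c("10" = 100, "11" = 30,
                                               "01" = 3, "00" = 3)) {
  if (is.null(cluster_sizes)) cluster_sizes <- integer(0)
  cluster_sizes <- cluster_sizes[cluster_sizes > 0]
  if (length(cluster_sizes) && is.null(names(cluster_sizes)))
    abort_arg("cluster_sizes must be named with labels a-h")
  if (sum(cluster_sizes) > nrow(genes))
    abort_arg("cluster_sizes oversubscribed: ", sum(cluster_sizes),
              " > ", nrow(genes), " genes")
  classes <- unname(conditions)
  if (!all(c("tissue", "short_term", "long_term") %in% classes))
    abort_arg("conditions must include tissue, short_term and long_term classes")
  n <- nrow(genes)
  labels <- rep("none", n)
  with_seed(substream_seed(seed, "scenario"), {
    pool <- sample.int(n)
    at <- 1L
    for (lab in names(cluster_sizes)) {
      k <- cluster_sizes[[lab]]
      labels[pool[at:(at + k - 1L)]] <- lab
      at <- at + k
    }
    states <- matrix("", n, length(conditions),
                     dimnames = list(genes$gene_id, names(conditions)))
    for (lab in setdiff(unique(labels), "none"))
      states[labels == lab, ] <- matrix(cluster_state(lab, classes),
                                        sum(labels == lab), length(classes),
                                        byrow = TRUE)
    canonical <- vapply(letters[1:8], function(l) cluster_state(l, classes),
                        character(length(classes)))
    for (i in which(labels == "none")) {
      repeat {
        s <- sample(MOD_STATES, length(classes), replace = TRUE)
        if (!any(colSums(canonical == s) == length(classes))) break
      }
      states[i, ] <- s
    }
    expr <- matrix(expr_state_mean[states], n, length(conditions),
                   dimnames = dimnames(states))
    structure(list(gene_id = genes$gene_id,
                   cluster_label = setNames(labels, genes$gene_id),
                   states = states, expr = expr, conditions = conditions),
              class = "planted_truth")
  })
}

#' Noise parameters for the peak emitter
#'
#' @param peak_dropout_prob Probability a true peak is missing from one
#'   replicate (per replicate, independent).
#' @param fe_meanlog,fe_sdlog Log-normal fold-enrichment parameters (median
#'   `exp(fe_meanlog)`); the distribution straddles the rescue threshold 5 so
#'   singleton peaks exercise the rescue rule in both directions.
#' @param breadth_range Uniform range of peak breadth in bases.
#' @param breadth_jitter Uniform +/- perturbation of each peak edge, per
#'   replicate, in bases.
#' @param body_peak_frac Fraction of peaks centred on the gene body rather
#'   than the promoter.
#' @param seed Root seed; each (mark, condition) emission uses a named
#'   substream of it.
#' @return List of class `noise_params`.
#' @export
noise_params <- function(peak_dropout_prob = 0.05, fe_meanlog = log(8),
                         fe_sdlog = 0.6, breadth_range = c(600, 1600),
                         breadth_jitter = 50, body_peak_frac = 0.1,
                         seed = 1L) {
  if (peak_dropout_prob < 0 || peak_dropout_prob > 1)
    abort_arg("peak_dropout_prob must be in [0, 1]")
  if (breadth_jitter < 0) abort_arg("breadth_jitter must be >= 0")
  structure(list(peak_dropout_prob = peak_dropout_prob,
                 fe_meanlog = fe_meanlog, fe_sdlog = fe_sdlog,
                 breadth_range = breadth_range,
                 breadth_jitter = breadth_jitter,
                 body_peak_frac = body_peak_frac, seed = seed),
            class = "noise_params")
}

mark_bit <- function(mark) {
  switch(mark, H3K4me3 = 1L, H3K27me3 = 2L,
         abort_arg("unknown mark: ", mark))
}

#' Emit two replicates of peak calls for one mark and condition
#'
#' Every gene whose planted state carries the mark in this condition gets one
#' peak per replicate, centred on its promoter (a configurable minority on
#' the gene body), unless dropped out. Peak attributes (breadth, fold
#' enrichment, tag density) are drawn once per gene and shared between
#' replicates, so with zero dropout and zero jitter the two replicate lists
#' are identical; dropout and edge jitter are per replicate. Dropout uses one
#' uniform draw per gene/replicate compared against `peak_dropout_prob`, so
#' raising the probability can only remove peaks (same seed stream per
#' decision).
#'
#' @param truth A `planted_truth` object.
#' @param genes The gene reference the truth was planted on.
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @param condition A condition id present in `truth$conditions`.
#' @param noise A [noise_params()] object.
#' @return List with elements `rep1` and `rep2`, each a peak `data.frame`
#'   (`chrom`, `start`, `end`, `breadth`, `fold_enrichment`, `tag_density`,
#'   `mark`, `sample_id`).
#' @export
emit_replicate_peaks <- function(truth, genes, mark, condition,
                                 noise = noise_params()) {
  bit <- mark_bit(mark)
  if (!condition %in% colnames(truth$states))
    abort_arg("unknown condition: ", condition)
  stopifnot(identical(truth$gene_id, genes$gene_id))
  carrier <- substr(truth$states[, condition], bit, bit) == "1"
  idx <- which(carrier)
  with_seed(substream_seed(noise$seed, paste("peaks", mark, condition)), {
    n <- length(idx)
    breadth <- round(runif(n, noise$breadth_range[1], noise$breadth_range[2]))
    fe <- rlnorm(n, noise$fe_meanlog, noise$fe_sdlog)
    density <- fe * runif(n, 5, 15)
    on_body <- runif(n) < noise$body_peak_frac
    tss <- ifelse(genes$strand[idx] == "+", genes$start[idx], genes$end[idx])
    center <- ifelse(on_body, (genes$start[idx] + genes$end[idx]) / 2, tss)
    reps <- lapply(1:2, function(r) {
      u_drop <- runif(n)
      j1 <- round(runif(n, -noise$breadth_jitter, noise$breadth_jitter))
      j2 <- round(runif(n, -noise$breadth_jitter, noise$breadth_jitter))
      keep <- u_drop >= noise$peak_dropout_prob
      s <- pmax(0, round(center - breadth / 2) + j1)
      e <- pmax(s + 1, round(center + breadth / 2) + j2)
      data.frame(chrom = genes$chrom[idx], start = s, end = e,
                 breadth = e - s, fold_enrichment = fe,
                 tag_density = density, mark = mark,
                 sample_id = paste0(condition, "_r", r),
                 stringsAsFactors = FALSE)[keep, , drop = FALSE]
    })
    names(reps) <- c("rep1", "rep2")
    reps
  })
}

#' Emit a negative-binomial count matrix coupled to planted states
#'
#' Counts for gene g in a sample of condition c are drawn from a
#' negative-binomial with mean proportional to the planted expression mean,
#' scaled so each sample's expected total equals `library_size`.
#'
#' @param truth A `planted_truth` object.
#' @param samples Data frame with columns `condition` and `replicate`; sample
#'   ids are `<condition>_r<replicate>`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); > 0.
#' @param library_size Expected total counts per sample.
#' @param seed Integer seed.
#' @return List with `counts` (gene x sample integer matrix), `lengths`
#'   (named gene lengths, if `genes` given) and `samples`.
#' @param genes Optional gene reference supplying gene lengths.
#' @export
emit_counts <- function(truth, samples, dispersion = 0.1,
                        library_size = 1e6, seed = 1L, genes = NULL) {
  if (nrow(samples) == 0L) abort_arg("samples must be non-empty")
  if (dispersion <= 0) abort_arg("dispersion must be > 0")
  if (!all(samples$condition %in% colnames(truth$expr)))
    abort_arg("unknown condition in samples")
  sample_id <- paste0(samples$condition, "_r", samples$replicate)
  with_seed(substream_seed(seed, "counts"), {
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      mu <- truth$expr[, samples$condition[j]]
      mu <- mu / sum(mu) * library_size
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }, numeric(length(truth$gene_id)))
    dimnames(counts) <- list(truth$gene_id, sample_id)
    lengths <- if (!is.null(genes)) setNames(genes$length, genes$gene_id)
    list(counts = counts, lengths = lengths,
         samples = cbind(samples, sample_id = sample_id))
  })
}
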