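# End-to-end orchestration over a synthetic scenario: simulate -> consensus
# -> encode -> SOM -> drift -> transcription, with every stage artifact
# written to disk and a JSON manifest recording parameters, seeds, file
# checksums and recovery metrics. Stages communicate only via files, so real
# peak lists or count matrices can be injected at any boundary.

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param n_genes Number of synthetic genes.
#' @param conditions Named condition -> class vector.
#' @param cluster_sizes Planted cluster sizes (labels a--h).
#' @param noise A [noise_params()] object.
#' @param fe_threshold Consensus rescue threshold (> 0).
#' @param rescue Whether the fold-enrichment rescue rule is active.
#' @param flank Promoter flank in bases.
#' @param min_overlap_frac Peak-to-gene overlap threshold in (0, 1].
#' @param pseudocount Log offset for expression statistics.
#' @param som_grid `c(rows, cols)` SOM grid.
#' @param som_epochs SOM training epochs.
#' @param dispersion,library_size RNA count emission parameters.
#' @param seed Root seed for every stochastic stage.
#' @return List of class `run_config`.
#' @export
drift_config <- function(out_dir = tempfile("epidrift_"), n_genes = 2000L,
                         conditions = default_conditions(),
                         cluster_sizes = c(c = 401L, d = 102L, e = 342L,
                                           f = 147L, g = 86L, h = 233L),
                         noise = noise_params(peak_dropout_prob = 0),
                         fe_threshold = 5.0, rescue = TRUE, flank = 1000,
                         min_overlap_frac = 0.05, pseudocount = 0.1,
                         som_grid = c(8L, 8L), som_epochs = 20L,
                         dispersion = 0.1, library_size = 1e6, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a configuration without executing it
#'
#' @param config A `run_config`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$n_genes >= 1, "n_genes must be >= 1")
  chk(config$min_overlap_frac > 0 && config$min_overlap_frac <= 1,
      "min_overlap_frac must be in (0, 1]")
  chk(config$fe_threshold > 0, "fe_threshold must be > 0")
  chk(config$flank >= 0, "flank must be >= 0")
  chk(config$pseudocount > 0, "pseudocount must be > 0")
  chk(config$dispersion > 0, "dispersion must be > 0")
  chk(all(config$som_grid >= 1), "som_grid must be >= 1x1")
  chk(sum(config$cluster_sizes) <= config$n_genes,
      "cluster_sizes oversubscribed")
  chk(all(c("tissue", "short_term", "long_term") %in% config$conditions),
      "conditions must cover tissue, short_term and long_term")
  v
}

#' Run the full pipeline on a synthetic scenario
#'
#' Executes simulate -> consensus -> encode -> SOM -> drift ->
#' transcription, writing every intermediate artifact under
#' `config$out_dir` and returning (and writing) a manifest with parameter
#' values, seeds, md5 checksums of all outputs and planted-truth recovery
#' metrics. Rerunning with the same config reproduces identical files.
#'
#' @param config A `run_config` from [drift_config()].
#' @return The manifest, invisibly also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues))
    abort_arg("invalid config: ", paste(issues, collapse = "; "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- "simulate"
  res <- tryCatch({
    genes <- generate_genome(config$n_genes, seed = config$seed)
    truth <- plant_scenario(genes, config$conditions, config$cluster_sizes,
                            seed = config$seed)
    write_gene_table(genes, out("genes.tsv"))
    write_matrix_tsv(truth$states, out("planted_states.tsv"))
    noise <- config$noise
    noise$seed <- config$seed

    stage <- "consensus"
    consensus <- list()
    for (cond in names(config$conditions)) {
      consensus[[cond]] <- list()
      for (mk in c("H3K4me3", "H3K27me3")) {
        reps <- emit_replicate_peaks(truth, genes, mk, cond, noise)
        cons <- build_summary_peaks(reps$rep1, reps$rep2,
                                    config$fe_threshold, config$rescue)
        write_peaks_bed(cons, out(sprintf("consensus_%s_%s.bed", cond, mk)))
        consensus[[cond]][[mk]] <- cons
      }
    }

    stage <- "encode"
    codes <- build_code_matrix(genes, consensus, config$min_overlap_frac,
                               config$flank)
    write_matrix_tsv(codes, out("code_matrix.tsv"))
    freqs <- state_frequencies(codes)
    write_matrix_tsv(freqs, out("state_frequencies.tsv"))

    stage <- "som"
    profiles <- codes_to_profiles(codes)
    som <- train_som(profiles, config$som_grid[1], config$som_grid[2],
                     epochs = config$som_epochs, seed = config$seed)
    write_matrix_tsv(som$weights, out("som_weights.tsv"))

    stage <- "drift"
    rules <- standard_rules(config$conditions)
    calls <- call_transitions(codes, rules)
    write.table(calls, out("drift_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    call_sets <- split(calls$gene_id, calls$label)
    write_gmt(call_sets[setdiff(names(call_sets), "unclassified")],
              out("drift_clusters.gmt"))

    stage <- "transcription"
    samples <- data.frame(condition = rep(names(config$conditions), each = 2),
                          replicate = 1:2)
    cnt <- emit_counts(truth, samples, config$dispersion,
                       config$library_size, config$seed, genes = genes)
    rk <- rpkm(rpm(cnt$counts), cnt$lengths)
    write_matrix_tsv(cnt$counts, out("counts.tsv"))
    write_matrix_tsv(round(rk, 4), out("rpkm.tsv"))

    planted <- truth$cluster_label[rownames(codes)]
    metrics <- recovery_metrics(planted, setNames(calls$label, calls$gene_id))
    list(genes = genes, truth = truth, codes = codes, som = som,
         calls = calls, rpkm = rk, metrics = metrics)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- setdiff(files, out("manifest.json"))
  manifest <- list(
    package = "epidrift",
    version = as.character(utils::packageVersion("epidrift")),
    seed = config$seed,
    parameters = config[c("n_genes", "fe_threshold", "rescue", "flank",
                          "min_overlap_frac", "pseudocount", "som_epochs",
                          "dispersion", "library_size")],
    cluster_sizes = as.list(config$cluster_sizes),
    recovery = res$metrics,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest, out_dir = config$out_dir)))
}

#' Emit, summarize and encode a planted scenario in one call
#'
#' Convenience wrapper over [emit_replicate_peaks()], [build_summary_peaks()]
#' and [build_code_matrix()]: emits two noisy replicates per condition and
#' mark, builds consensus lists, and encodes the per-gene modification
#' codes.
#'
#' @param truth A `planted_truth`.
#' @param genes Its gene reference.
#' @param noise A [noise_params()].
#' @param fe_threshold,rescue Consensus parameters.
#' @param min_overlap_frac,flank Coding parameters.
#' @return A `code_matrix` with one column per condition.
#' @export
encode_scenario <- function(truth, genes, noise = noise_params(),
                            fe_threshold = 5.0, rescue = TRUE,
                            min_overlap_frac = 0.05, flank = 1000) {
  consensus <- list()
  for (cond in names(truth$conditions)) {
    consensus[[cond]] <- list()
    for (mk in c("H3K4me3", "H3K27me3")) {
      reps <- emit_replicate_peaks(truth, genes, mk, cond, noise)
      consensus[[cond]][[mk]] <-
        build_summary_peaks(reps$rep1, reps$rep2, fe_threshold, rescue)
    }
  }
  build_code_matrix(genes, consensus, min_overlap_frac, flank)
}

#' Precision and recall of drift calls against planted labels
#'
#' @param planted Named vector gene_id -> planted label (`none` allowed).
#' @param called Named vector gene_id -> called label (`unclassified`
#'   allowed).
#' @return Data frame with per-label `planted_n`, `called_n`, `precision`,
#'   `recall`.
#' @export
recovery_metrics <- function(planted, called) {
  called <- called[names(planted)]
  labs <- sort(setdiff(unique(planted), "none"))
  do.call(rbind, lapply(labs, function(l) {
    tp <- sum(planted == l & called == l, na.rm = TRUE)
    data.frame(label = l, planted_n = sum(planted == l),
               called_n = sum(called == l, na.rm = TRUE),
               precision = if (sum(called == l, na.rm = TRUE)) tp / sum(called == l, na.rm = TRUE) else NA_real_,
               recall = tp / sum(planted == l), stringsAsFactors = FALSE)
  }))
}
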