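test_that("generate_genome: layout, determinism, sex-chromosome fraction", {
  g1 <- generate_genome(1, n_autosomes = 1, seed = 1)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$chrom, "chr1")
  expect_true(g1$start < g1$end && g1$length == g1$end - g1$start)

  a <- generate_genome(100, seed = 7)
  b <- generate_genome(100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_genome(100, seed = 8)))

  # genes non-overlapping within every chromosome
  for (ch in unique(a$chrom)) {
    gc <- a[a$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1) expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }

  s <- generate_genome(1000, include_sex_chroms = TRUE, sex_fraction = 0.1,
                       seed = 3)
  n_sex <- sum(s$chrom %in% c("chrX", "chrY"))
  expect_gt(n_sex, 60); expect_lt(n_sex, 140)

  expect_error(generate_genome(0), "n_genes")
  expect_error(generate_genome(5, n_autosomes = 0), "n_autosomes")
})

test_that("plant_scenario: planted states follow the cluster definitions", {
  genes <- generate_genome(300, seed = 2)
  conds <- default_conditions()
  sizes <- c(a = 20, b = 10, c = 30, d = 20, e = 25, f = 15, g = 20, h = 25)
  tr <- plant_scenario(genes, conds, sizes, seed = 5)

  expect_equal(unname(table(tr$cluster_label)[names(sizes)]),
               unname(sizes), ignore_attr = TRUE)
  tissue <- names(conds)[conds == "tissue"]
  short <- names(conds)[conds == "short_term"]
  long <- names(conds)[conds == "long_term"]
  for (gid in names(tr$cluster_label)[tr$cluster_label == "g"]) {
    expect_true(all(tr$states[gid, c(tissue, short)] == "11"))
    expect_true(all(tr$states[gid, long] == "10"))
  }
  for (gid in names(tr$cluster_label)[tr$cluster_label == "c"]) {
    expect_true(all(tr$states[gid, tissue] == "10"))
    expect_true(all(tr$states[gid, c(short, long)] == "00"))
  }
  # expression coupling direction: (10) high, (11) mid, (01)/(00) low
  ex <- tr$expr
  st <- tr$states
  expect_gt(min(ex[st == "10"]), max(ex[st == "11"]))
  expect_gt(min(ex[st == "11"]), max(ex[st == "01"]))

  empty <- plant_scenario(genes, conds, cluster_sizes = NULL, seed = 1)
  expect_true(all(empty$cluster_label == "none"))
  expect_error(plant_scenario(genes, conds, c(a = 400), seed = 1),
               "oversubscribed")
})

test_that("unlabelled genes never realise a planted cluster pattern", {
  genes <- generate_genome(500, seed = 9)
  tr <- plant_scenario(genes, cluster_sizes = c(c = 20, g = 20), seed = 9)
  rules <- standard_rules(tr$conditions)
  codes <- structure(tr$states, class = c("code_matrix", class(tr$states)))
  calls <- call_transitions(codes, rules)
  lab <- setNames(calls$label, calls$gene_id)
  none <- names(tr$cluster_label)[tr$cluster_label == "none"]
  expect_true(all(lab[none] == "unclassified"))
})

test_that("emit_replicate_peaks: zero noise, dropout and determinism", {
  sc <- small_scenario(n_genes = 120, cluster_sizes = c(c = 30, g = 30),
                       seed = 4)
  clean <- noise_params(peak_dropout_prob = 0, breadth_jitter = 0, seed = 4)
  reps <- emit_replicate_peaks(sc$truth, sc$genes, "H3K4me3", "tissue_1", clean)
  drop_id <- function(p) p[, setdiff(names(p), "sample_id")]
  expect_identical(drop_id(reps$rep1), drop_id(reps$rep2))
  reps2 <- emit_replicate_peaks(sc$truth, sc$genes, "H3K4me3", "tissue_1", clean)
  expect_identical(reps, reps2)

  # every gene carrying the mark gets a promoter-overlapping peak
  carriers <- substr(sc$truth$states[, "tissue_1"], 1, 1) == "1"
  expect_equal(nrow(reps$rep1), sum(carriers))

  gone <- emit_replicate_peaks(sc$truth, sc$genes, "H3K27me3", "tissue_1",
                               noise_params(peak_dropout_prob = 1, seed = 4))
  expect_equal(nrow(gone$rep1), 0L)
  expect_equal(nrow(gone$rep2), 0L)

  # bivalent gene: peak in both marks for at least one replicate
  biv <- which(sc$truth$states[, "tissue_1"] == "11")[1]
  gid_start <- sc$genes$start[biv]
  k4 <- emit_replicate_peaks(sc$truth, sc$genes, "H3K4me3", "tissue_1", clean)
  k27 <- emit_replicate_peaks(sc$truth, sc$genes, "H3K27me3", "tissue_1", clean)
  near <- function(p) any(p$chrom == sc$genes$chrom[biv] &
                          abs((p$start + p$end) / 2 - gid_start) < 5e4)
  expect_true(near(k4$rep1) || near(k4$rep2))
  expect_true(near(k27$rep1) || near(k27$rep2))

  expect_error(emit_replicate_peaks(sc$truth, sc$genes, "H3K9me3", "tissue_1"),
               "unknown mark")
  expect_error(emit_replicate_peaks(sc$truth, sc$genes, "H3K4me3", "nope"),
               "unknown condition")
})

test_that("dropout monotonicity: raising dropout never adds peaks", {
  sc <- small_scenario(n_genes = 200, cluster_sizes = c(a = 100), seed = 6)
  probs <- c(0, 0.1, 0.3, 0.6, 1)
  counts <- vapply(probs, function(p) {
    reps <- emit_replicate_peaks(sc$truth, sc$genes, "H3K4me3", "tissue_1",
                                 noise_params(peak_dropout_prob = p, seed = 6))
    nrow(reps$rep1) + nrow(reps$rep2)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # same seed stream: peaks surviving at higher dropout are a subset
  r_lo <- emit_replicate_peaks(sc$truth, sc$genes, "H3K4me3", "tissue_1",
                               noise_params(peak_dropout_prob = 0.1, seed = 6))
  r_hi <- emit_replicate_peaks(sc$truth, sc$genes, "H3K4me3", "tissue_1",
                               noise_params(peak_dropout_prob = 0.5, seed = 6))
  expect_true(all(r_hi$rep1$start %in% r_lo$rep1$start))
})

test_that("emit_counts: determinism, zero rows, mean recovery", {
  sc <- small_scenario(n_genes = 150, cluster_sizes = c(c = 40, f = 40),
                       seed = 8)
  samples <- data.frame(condition = rep(c("tissue_1", "organoid_L_wt"), each = 2),
                        replicate = 1:2)
  c1 <- emit_counts(sc$truth, samples, seed = 3)
  c2 <- emit_counts(sc$truth, samples, seed = 3)
  expect_identical(c1$counts, c2$counts)
  expect_false(identical(c1$counts, emit_counts(sc$truth, samples, seed = 4)$counts))

  tr0 <- sc$truth
  tr0$expr[1, ] <- 0
  z <- emit_counts(tr0, samples, seed = 3)
  expect_true(all(z$counts[1, ] == 0))

  # low dispersion, many replicates: scaled row means approach planted means
  many <- data.frame(condition = "tissue_1", replicate = 1:40)
  cc <- emit_counts(sc$truth, many, dispersion = 1e-3, library_size = 2e5,
                    seed = 5)
  mu <- sc$truth$expr[, "tissue_1"]
  expected <- mu / sum(mu) * 2e5
  obs <- rowMeans(cc$counts)
  big <- expected > 50
  expect_lt(max(abs(obs[big] - expected[big]) / expected[big]), 0.1)

  expect_error(emit_counts(sc$truth, samples[0, ]), "non-empty")
  expect_error(emit_counts(sc$truth, samples, dispersion = 0), "dispersion")
})
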