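gauss_profiles <- function(n = 200, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("g", seq_len(n)), paste0("s", seq_len(p))))
  x
}

test_that("train_som basics: determinism, identical profiles, validation", {
  x <- gauss_profiles()
  s1 <- train_som(x, 4, 4, epochs = 10, seed = 5)
  s2 <- train_som(x, 4, 4, epochs = 10, seed = 5)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$gene_to_unit, s2$gene_to_unit)

  x2 <- rbind(x, dup = x[1, ])
  s3 <- train_som(x2, 4, 4, epochs = 10, seed = 5)
  expect_equal(unname(s3$gene_to_unit["dup"]), unname(s3$gene_to_unit["g1"]))

  xb <- x; xb[1, 1] <- NA
  expect_error(train_som(xb, 2, 2), "finite")
  expect_error(train_som(x[, 1, drop = FALSE], 2, 2), ">= 2")
})

test_that("1x1 grid converges to the column means", {
  x <- gauss_profiles(150, 5, seed = 2)
  s <- train_som(x, 1, 1, epochs = 5, init = "linear")
  expect_equal(as.numeric(s$weights), unname(colMeans(x)), tolerance = 1e-6)
})

test_that("zero-neighborhood batch SOM equals Lloyd k-means", {
  x <- gauss_profiles(300, 6, seed = 3)
  set.seed(10)
  w0 <- unname(x[sample.int(nrow(x), 4), ])
  s <- train_som(x, 2, 2, epochs = 80, radius_start = 0, radius_end = 0,
                 init = w0)
  km <- kmeans(x, centers = w0, iter.max = 200, algorithm = "Lloyd")
  expect_lt(km$iter, 200)  # converged, so the comparison is meaningful
  expect_equal(unname(s$gene_to_unit), unname(km$cluster))
  expect_equal(unname(s$weights), unname(km$centers), tolerance = 1e-10)
})

test_that("quantization error is non-increasing over epochs", {
  x <- gauss_profiles(400, 8, seed = 4)
  for (ini in c("sample", "uniform", "linear")) {
    s <- train_som(x, 8, 8, epochs = 20, init = ini, seed = 2)
    expect_true(all(diff(s$qe) <= 1e-9), label = paste("init", ini))
  }
})

test_that("sample_portrait reshapes metagene values", {
  x <- gauss_profiles(100, 4, seed = 5)
  x[, 4] <- x[, 3]  # duplicated sample
  s <- train_som(x, 3, 5, epochs = 8, seed = 1)
  p3 <- sample_portrait(s, "s3"); p4 <- sample_portrait(s, "s4")
  expect_equal(dim(p3), c(3L, 5L))
  expect_equal(p3, p4)
  expect_error(sample_portrait(s, "nope"), "unknown column")

  flatx <- matrix(1, 50, 3, dimnames = list(paste0("g", 1:50), paste0("s", 1:3)))
  sf <- train_som(flatx, 2, 2, epochs = 5, init = "linear")
  expect_equal(diff(range(sample_portrait(sf, "s1"))), 0)
})

test_that("correlation clusters: degenerate cases and planted separation", {
  flatx <- matrix(rep(c(1, 2, 3), each = 40), 40, 3,
                  dimnames = list(paste0("g", 1:40), paste0("s", 1:3)))
  s <- train_som(flatx, 3, 3, epochs = 5, init = "linear")
  cc <- correlation_clusters(s, threshold = 0.9)
  expect_length(cc$spots, 1)
  expect_length(cc$spots[[1]], 9)
  expect_length(correlation_clusters(s, threshold = 1.5)$spots, 0)

  # zero-noise planted labels a-f separate into distinct spots
  sc <- small_scenario(n_genes = 240,
                       cluster_sizes = c(a = 40, b = 40, c = 40, d = 40,
                                         e = 40, f = 40), seed = 17)
  prof <- codes_to_profiles(structure(sc$truth$states,
                                      class = c("code_matrix", "matrix")))
  som <- train_som(prof, 8, 8, epochs = 30, seed = 17)
  cc <- correlation_clusters(som, threshold = 0.9)
  spot_of <- function(gids) {
    hits <- which(vapply(cc$member_genes, function(m) any(gids %in% m),
                         logical(1)))
    expect_length(hits, 1)
    # Jaccard with the planted set
    j <- length(intersect(cc$member_genes[[hits]], gids)) /
      length(union(cc$member_genes[[hits]], gids))
    expect_gte(j, 0.9)
    hits
  }
  labs <- sc$truth$cluster_label
  spots <- vapply(letters[1:6], function(l)
    spot_of(names(labs)[labs == l]), numeric(1))
  expect_equal(length(unique(spots)), 6L)
})

test_that("under-expression spots recover the long-term activations g and h", {
  sc <- small_scenario(n_genes = 320,
                       cluster_sizes = c(a = 60, b = 40, f = 40, g = 40,
                                         h = 40), seed = 23)
  prof <- codes_to_profiles(structure(sc$truth$states,
                                      class = c("code_matrix", "matrix")))
  som <- train_som(prof, 8, 8, epochs = 30, seed = 23)
  conds <- sc$truth$conditions
  early <- names(conds)[conds != "long_term"]
  late <- names(conds)[conds == "long_term"]
  labs <- sc$truth$cluster_label
  # g: K27 drops in long-term while high before
  sg <- underexpression_spots(som, group_low = paste0(late, ".K27"),
                              group_high = paste0(early, ".K27"),
                              quantile = 0.25)
  got_g <- unique(unlist(sg$member_genes))
  expect_gte(mean(names(labs)[labs == "g"] %in% got_g), 0.9)
  # h: K4 low before long-term, high in long-term
  sh <- underexpression_spots(som, group_low = paste0(early, ".K4"),
                              group_high = paste0(late, ".K4"),
                              quantile = 0.25)
  got_h <- unique(unlist(sh$member_genes))
  expect_gte(mean(names(labs)[labs == "h"] %in% got_h), 0.9)

  # constant map has no spots
  flatx <- matrix(1, 30, 4, dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  sf <- train_som(flatx, 2, 2, epochs = 3, init = "linear")
  expect_length(underexpression_spots(sf, "s1", "s2")$spots, 0)

  # lowering the quantile never grows the selected unit set
  units_at <- function(q) sort(unlist(underexpression_spots(
    som, paste0(late, ".K27"), paste0(early, ".K27"), quantile = q)$spots))
  u1 <- units_at(0.25); u2 <- units_at(0.15); u3 <- units_at(0.05)
  expect_true(all(u2 %in% u1))
  expect_true(all(u3 %in% u2))
})

test_that("kmeans_landscape partitions every unit", {
  x <- gauss_profiles(150, 5, seed = 6)
  s <- train_som(x, 4, 4, epochs = 10, seed = 1)
  k1 <- kmeans_landscape(s, 1)
  expect_length(k1$spots, 1)
  expect_length(k1$spots[[1]], 16)
  kk <- kmeans_landscape(s, 16)
  expect_length(kk$spots, 16)
  k4a <- kmeans_landscape(s, 4, seed = 3)
  k4b <- kmeans_landscape(s, 4, seed = 3)
  expect_identical(k4a$spots, k4b$spots)
  expect_setequal(unlist(k4a$spots), 1:16)
  expect_error(kmeans_landscape(s, 17), "exceeds")
})

test_that("correlation spanning tree matches brute force on triples", {
  x <- gauss_profiles(100, 2, seed = 7)
  s2 <- train_som(x, 3, 3, epochs = 8, seed = 1)
  tr <- correlation_spanning_tree(s2)
  expect_equal(nrow(tr), 1L)

  set.seed(31)
  for (rep in 1:25) {
    w <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
    s <- list(weights = w, columns = colnames(w))
    class(s) <- "som_model"
    tree <- correlation_spanning_tree(s)
    cm <- cor(w)
    # enumerate the three spanning trees of K3 by total distance
    combos <- list(c("AB", "AC"), c("AB", "BC"), c("AC", "BC"))
    dd <- c(AB = 1 - cm["A", "B"], AC = 1 - cm["A", "C"], BC = 1 - cm["B", "C"])
    best <- combos[[which.min(vapply(combos, function(e) sum(dd[e]), numeric(1)))]]
    got <- sort(vapply(seq_len(nrow(tree)), function(k)
      paste(sort(c(tree$from[k], tree$to[k])), collapse = ""), character(1)))
    expect_equal(got, sort(best))
  }
  expect_error(correlation_spanning_tree(s2, columns = "s1"), ">= 2")
})

test_that("cutting the two longest edges recovers planted expression groups", {
  set.seed(41)
  n <- 300
  centers <- list(G1 = rnorm(n, 0), G2 = rnorm(n, 0), G3 = rnorm(n, 0))
  samples <- c(G1_a = "G1", G1_b = "G1", G1_c = "G1",
               G2_a = "G2", G2_b = "G2", G2_c = "G2",
               G3_a = "G3", G3_b = "G3", G3_c = "G3")
  x <- vapply(names(samples), function(s)
    centers[[samples[[s]]]] + rnorm(n, sd = 0.2), numeric(n))
  rownames(x) <- paste0("g", 1:n)
  som <- train_som(x, 6, 6, epochs = 15, seed = 2)
  tree <- correlation_spanning_tree(som)
  groups <- cut_spanning_tree(tree, 2)
  expect_length(groups, 3)
  got <- lapply(groups, function(g) sort(unname(samples[g])))
  expect_setequal(vapply(got, function(g) paste(unique(g), collapse = ""),
                         character(1)), c("G1", "G2", "G3"))
  expect_true(all(vapply(got, function(g) length(unique(g)) == 1, logical(1))))
})
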