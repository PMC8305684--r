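# Self-organizing map over per-gene multi-sample profiles. Batch training
# with a Gaussian neighborhood whose radius decays linearly; at radius zero
# the update reduces to Lloyd's k-means, which anchors the reference checks.

#' Expand a code matrix to numeric SOM profiles
#'
#' Each sample becomes two columns, `<sample>.K4` and `<sample>.K27`, holding
#' the two bits as 0/1 values, so a metagene's value is directly readable as
#' an average modification level.
#'
#' @param codes A `code_matrix`.
#' @return Numeric gene x (2 * samples) matrix.
#' @export
codes_to_profiles <- function(codes) {
  k4 <- matrix(as.numeric(substr(codes, 1, 1)), nrow(codes))
  k27 <- matrix(as.numeric(substr(codes, 2, 2)), nrow(codes))
  out <- matrix(0, nrow(codes), 2L * ncol(codes))
  out[, seq(1, ncol(out), 2)] <- k4
  out[, seq(2, ncol(out), 2)] <- k27
  dimnames(out) <- list(rownames(codes),
                        paste0(rep(colnames(codes), each = 2), c(".K4", ".K27")))
  out
}

unit_positions <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), times = cols),
        col = rep(seq_len(cols), each = rows))
}

# Squared Euclidean distances between data rows and unit weights.
cross_dist2 <- function(x, w) {
  outer(rowSums(x^2), rowSums(w^2), "+") - 2 * x %*% t(w)
}

bmu_of <- function(x, w) max.col(-cross_dist2(x, w), ties.method = "first")

#' Train a batch self-organizing map
#'
#' Standard batch SOM: per epoch, every gene is assigned its best-matching
#' unit (BMU, Euclidean distance, ties to the lowest unit index) and each
#' unit's weight is replaced by the neighborhood-weighted mean of the data,
#' with a Gaussian neighborhood whose radius decays linearly from
#' `radius_start` (default: half the grid diagonal) to `radius_end`. With
#' `radius_start = radius_end = 0` this is exactly Lloyd's k-means on the
#' initial weights. Deterministic for a fixed seed.
#'
#' @param profiles Numeric gene x sample matrix (rownames = gene ids).
#' @param grid_rows,grid_cols Grid size (default 30 x 30).
#' @param epochs Training epochs.
#' @param radius_start,radius_end Neighborhood radius schedule in grid units.
#' @param init `"sample"` (weights initialised from random data rows),
#'   `"uniform"` (uniform in each column's data range) or `"linear"`
#'   (deterministic initialisation on the plane of the first two principal
#'   components — the conventional choice when a monotone quantization-error
#'   trajectory matters). A units x column numeric matrix may be supplied
#'   instead to fix the initial weights exactly.
#' @param seed Integer seed for the initialisation.
#' @return Object of class `som_model`: `weights` (unit x column matrix),
#'   `grid` (rows, cols), `pos` (unit grid positions), `gene_to_unit`
#'   (named integer), `qe` (mean gene-to-BMU distance achieved after each
#'   epoch's weight update, length `epochs`), `columns`.
#' @export
train_som <- function(profiles, grid_rows = 30L, grid_cols = 30L, epochs = 20L,
                      radius_start = NULL, radius_end = 0.5,
                      init = c("sample", "uniform", "linear"), seed = 1L) {
  init_matrix <- NULL
  if (is.matrix(init)) { init_matrix <- init; init <- "sample" }
  else init <- match.arg(init)
  x <- as.matrix(profiles)
  if (nrow(x) < 1L || ncol(x) < 2L) abort_arg("need >= 1 gene and >= 2 columns")
  if (any(!is.finite(x))) abort_arg("profiles must be finite")
  n_units <- as.integer(grid_rows) * as.integer(grid_cols)
  pos <- unit_positions(grid_rows, grid_cols)
  if (is.null(radius_start)) radius_start <- sqrt(grid_rows^2 + grid_cols^2) / 2
  w <- if (!is.null(init_matrix)) {
    stopifnot(nrow(init_matrix) == n_units, ncol(init_matrix) == ncol(x))
    init_matrix
  } else with_seed(substream_seed(seed, "som-init"), {
    switch(init,
      sample = x[sample.int(nrow(x), n_units, replace = nrow(x) < n_units), , drop = FALSE],
      uniform = apply(x, 2, function(col) runif(n_units, min(col), max(col))),
      linear = {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        sv <- svd(xc, nu = 0, nv = 2)
        pc <- cbind(sv$v, matrix(0, ncol(x), max(0, 2 - ncol(sv$v))))
        sdv <- c(sv$d, 0, 0)[1:2] / sqrt(max(1, nrow(x) - 1))
        u1 <- if (grid_rows > 1) (pos[, 1] - mean(pos[, 1])) / (grid_rows / 2) else rep(0, n_units)
        u2 <- if (grid_cols > 1) (pos[, 2] - mean(pos[, 2])) / (grid_cols / 2) else rep(0, n_units)
        rep(1, n_units) %o% mu + (u1 * sdv[1]) %o% pc[, 1] + (u2 * sdv[2]) %o% pc[, 2]
      })
  })
  w <- matrix(as.numeric(w), n_units, ncol(x))
  grid_d2 <- as.matrix(dist(pos))^2
  qe <- numeric(epochs)
  sigma <- if (epochs > 1L)
    seq(radius_start, radius_end, length.out = epochs) else radius_end
  for (ep in seq_len(epochs)) {
    d2 <- cross_dist2(x, w)
    bmu <- max.col(-d2, ties.method = "first")
    if (ep > 1L) qe[ep - 1L] <- mean(sqrt(pmax(0, d2[cbind(seq_len(nrow(x)), bmu)])))
    s <- sigma[ep]
    if (s > 0) {
      h <- exp(-grid_d2 / (2 * s^2))   # units x units
      hx <- h[, bmu, drop = FALSE]     # units x genes
      denom <- rowSums(hx)
      num <- hx %*% x
      upd <- denom > 0
      w[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
    } else {
      for (u in unique(bmu)) w[u, ] <- colMeans(x[bmu == u, , drop = FALSE])
    }
  }
  d2 <- cross_dist2(x, w)
  bmu <- max.col(-d2, ties.method = "first")
  qe[epochs] <- mean(sqrt(pmax(0, d2[cbind(seq_len(nrow(x)), bmu)])))
  dimnames(w) <- list(sprintf("unit_%04d", seq_len(n_units)), colnames(x))
  structure(list(weights = w, grid = c(rows = grid_rows, cols = grid_cols),
                 pos = pos,
                 gene_to_unit = setNames(bmu, rownames(x)),
                 qe = qe, columns = colnames(x)),
            class = "som_model")
}

#' One sample's SOM portrait
#'
#' @param som A `som_model`.
#' @param column A training column name (for code-derived SOMs,
#'   `<sample>.K4` / `<sample>.K27`).
#' @return `grid_rows` x `grid_cols` numeric matrix of metagene values.
#' @export
sample_portrait <- function(som, column) {
  j <- match(column, som$columns)
  if (is.na(j)) abort_arg("unknown column: ", column)
  out <- matrix(NA_real_, som$grid["rows"], som$grid["cols"])
  out[som$pos] <- som$weights[, j]
  out
}

# 8-neighborhood adjacency between a set of unit indices.
grid_components <- function(units, pos) {
  if (length(units) == 0L) return(list())
  comp <- rep(NA_integer_, length(units))
  adj <- abs(outer(pos[units, 1], pos[units, 1], "-")) <= 1 &
         abs(outer(pos[units, 2], pos[units, 2], "-")) <= 1
  cid <- 0L
  for (i in seq_along(units)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & is.na(comp))
      comp[nb] <- cid
      frontier <- c(frontier[-1], nb)
    }
  }
  split(units, comp)
}

spot_set <- function(spots, som, kind) {
  members <- lapply(spots, function(u)
    names(som$gene_to_unit)[som$gene_to_unit %in% u])
  structure(list(spots = spots, member_genes = members, kind = kind),
            class = "spot_set")
}

safe_cor <- function(a, b) {
  if (isTRUE(all.equal(a, b))) return(1)
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Correlation clusters of SOM units
#'
#' Connected components (8-neighborhood) of grid-adjacent units whose
#' metagene profiles correlate at or above `threshold`; identical profiles
#' count as correlation 1 even when constant. Member genes are the genes
#' whose BMU lies in the component.
#'
#' @param som A `som_model`.
#' @param threshold Pearson correlation threshold; values > 1 yield no
#'   clusters.
#' @param occupied_only If `TRUE`, only units that are BMU of at least one
#'   gene participate.
#' @return A `spot_set` of kind `correlation_cluster`.
#' @export
correlation_clusters <- function(som, threshold = 0.9, occupied_only = FALSE) {
  if (threshold > 1) return(spot_set(list(), som, "correlation_cluster"))
  units <- if (occupied_only) sort(unique(som$gene_to_unit))
           else seq_len(nrow(som$weights))
  if (!length(units)) return(spot_set(list(), som, "correlation_cluster"))
  n <- length(units)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (abs(som$pos[units[i], 1] - som$pos[units[j], 1]) <= 1 &&
        abs(som$pos[units[i], 2] - som$pos[units[j], 2]) <= 1 &&
        safe_cor(som$weights[units[i], ], som$weights[units[j], ]) >= threshold)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L; frontier <- i; comp[i] <- cid
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & is.na(comp))
      comp[nb] <- cid
      frontier <- c(frontier[-1], nb)
    }
  }
  spot_set(split(units, comp), som, "correlation_cluster")
}

#' Under-expression spots with a group contrast
#'
#' Selects units whose mean metagene value over `group_low` columns is at or
#' below the `quantile` quantile of that value across units, and not low
#' (above the `contrast_quantile` quantile) over `group_high` columns;
#' connected selections form spots. This picks up small unit sets that drop
#' in one sample group but not another, the signature of the long-term-only
#' transitions. Lowering `quantile` can only shrink spots (the contrast
#' side uses its own fixed quantile).
#'
#' @param som A `som_model`.
#' @param group_low,group_high Character vectors of training column names.
#' @param quantile Lowness quantile for `group_low` (default 0.25).
#' @param contrast_quantile Fixed quantile above which `group_high` counts
#'   as "not low" (default 0.5).
#' @return A `spot_set` of kind `underexpression_spot`.
#' @export
underexpression_spots <- function(som, group_low, group_high,
                                  quantile = 0.25, contrast_quantile = 0.5) {
  jl <- match(group_low, som$columns); jh <- match(group_high, som$columns)
  if (anyNA(jl) || anyNA(jh)) abort_arg("unknown column in group")
  v_low <- rowMeans(som$weights[, jl, drop = FALSE])
  v_high <- rowMeans(som$weights[, jh, drop = FALSE])
  if (diff(range(v_low)) == 0 && diff(range(v_high)) == 0)
    return(spot_set(list(), som, "underexpression_spot"))
  sel <- v_low <= stats::quantile(v_low, quantile) &
         v_high > stats::quantile(v_high, contrast_quantile)
  spot_set(grid_components(which(sel), som$pos), som, "underexpression_spot")
}

#' K-means partition of the SOM landscape
#'
#' @param som A `som_model`.
#' @param k Number of clusters (1..number of units).
#' @param seed Integer seed.
#' @return A `spot_set` of kind `kmeans_cluster` covering every unit.
#' @export
kmeans_landscape <- function(som, k, seed = 1L) {
  n_units <- nrow(som$weights)
  if (k < 1L) abort_arg("k must be >= 1")
  if (k > n_units) abort_arg("k exceeds the number of units")
  cl <- if (k == n_units) seq_len(n_units)
        else if (k == 1L) rep(1L, n_units)
        else with_seed(substream_seed(seed, "kmeans"), {
          centers <- som$weights[sample.int(n_units, k), , drop = FALSE]
          centers <- centers + matrix(rnorm(length(centers), sd = 1e-9), k)
          kmeans(som$weights, centers = centers, iter.max = 100,
                 algorithm = "Lloyd")$cluster
        })
  spot_set(split(seq_len(n_units), cl), som, "kmeans_cluster")
}

#' Maximum-correlation spanning tree of samples
#'
#' Minimum spanning tree (Prim's algorithm) on 1 - Pearson correlation of
#' the sample portraits (columns of the metagene weight matrix).
#'
#' @param som A `som_model`, trained on >= 2 columns.
#' @param columns Optional subset of training columns (default all).
#' @return Data frame of tree edges: `from`, `to`, `correlation`,
#'   `distance`.
#' @export
correlation_spanning_tree <- function(som, columns = NULL) {
  cols <- if (is.null(columns)) som$columns else columns
  j <- match(cols, som$columns)
  if (anyNA(j)) abort_arg("unknown column")
  if (length(j) < 2L) abort_arg("need >= 2 samples")
  cm <- cor(som$weights[, j, drop = FALSE])
  mst_edges(1 - cm, cols, cm)
}

# Prim's MST over a symmetric distance matrix; returns the edge list.
mst_edges <- function(d, labels, cm = NULL) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- NULL
  while (sum(in_tree) < n) {
    best <- c(Inf, NA, NA)
    for (i in which(in_tree)) for (k in which(!in_tree))
      if (d[i, k] < best[1]) best <- c(d[i, k], i, k)
    in_tree[best[3]] <- TRUE
    edges <- rbind(edges, best)
  }
  data.frame(from = labels[edges[, 2]], to = labels[edges[, 3]],
             correlation = if (is.null(cm)) 1 - edges[, 1]
                           else cm[cbind(edges[, 2], edges[, 3])],
             distance = edges[, 1], stringsAsFactors = FALSE)
}

#' Sample groups from cutting the longest tree edges
#'
#' Removes the `n_cut` largest-distance edges from a spanning tree and
#' returns the resulting connected components — the unsupervised sample
#' groups (e.g. G1/G2/G3).
#'
#' @param tree Edge data frame from [correlation_spanning_tree()].
#' @param n_cut Number of edges to remove.
#' @return List of character vectors of sample ids, one per component.
#' @export
cut_spanning_tree <- function(tree, n_cut) {
  keep <- tree[order(-tree$distance), ][-seq_len(n_cut), , drop = FALSE]
  nodes <- unique(c(tree$from, tree$to))
  comp <- setNames(seq_along(nodes), nodes)
  for (k in seq_len(nrow(keep))) {
    a <- comp[keep$from[k]]; b <- comp[keep$to[k]]
    comp[comp == b] <- a
  }
  unname(split(names(comp), comp))
}
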