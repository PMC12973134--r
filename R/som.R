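#' Self-organising map grid
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param topology `"toroidal"` (edges wrap) or `"planar"`.
#' @param neighbourhood `"gaussian"` or `"bubble"` kernel.
#' @return A list of class `som_grid`.
#' @export
som_grid <- function(rows = 16, cols = 16,
                     topology = c("toroidal", "planar"),
                     neighbourhood = c("gaussian", "bubble")) {
  topology <- match.arg(topology)
  neighbourhood <- match.arg(neighbourhood)
  stopifnot(rows >= 1, cols >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 topology = topology, neighbourhood = neighbourhood),
            class = "som_grid")
}

## Node index -> (row, col), both 0-based; nodes are numbered row-major from 1.
node_coords <- function(grid, node) {
  node <- as.integer(node)
  if (any(node < 1 | node > grid$rows * grid$cols)) stop("node off grid")
  cbind(row = (node - 1L) %/% grid$cols, col = (node - 1L) %% grid$cols)
}

#' Chebyshev distance between grid nodes, with toroidal wrap-around
#'
#' `max(min(|dr|, rows - |dr|), min(|dc|, cols - |dc|))` for toroidal grids;
#' plain Chebyshev distance for planar ones. Vectorised over node pairs.
#'
#' @param grid a [som_grid()].
#' @param node_a,node_b node indices (1-based, row-major).
#' @return Integer distances.
#' @export
toroidal_distance <- function(grid, node_a, node_b) {
  a <- node_coords(grid, node_a)
  b <- node_coords(grid, node_b)
  dr <- abs(a[, "row"] - b[, "row"])
  dc <- abs(a[, "col"] - b[, "col"])
  if (grid$topology == "toroidal") {
    dr <- pmin(dr, grid$rows - dr)
    dc <- pmin(dc, grid$cols - dc)
  }
  as.integer(pmax(dr, dc))
}

## All-pairs grid distance matrix (nodes x nodes).
grid_distance_matrix <- function(grid) {
  n <- grid$rows * grid$cols
  idx <- seq_len(n)
  outer(idx, idx, function(i, j) toroidal_distance(grid, i, j))
}

## Best-matching units by squared Euclidean distance; ties -> lowest index.
bmu_of <- function(X, codebook, second = FALSE) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2 ; ||x||^2 constant per gene
  cross <- X %*% t(codebook)
  d2 <- sweep(-2 * cross, 2, rowSums(codebook^2), "+")
  first <- max.col(-d2, ties.method = "first")
  if (!second) return(first)
  d2[cbind(seq_len(nrow(d2)), first)] <- Inf
  cbind(first = first, second = max.col(-d2, ties.method = "first"))
}

#' Train a batch self-organising map on gene profiles
#'
#' Genes (rows of `X`, standardised to mean 0 / SD 1 across samples) are
#' quantised onto the grid. Each epoch assigns every gene to its best-matching
#' unit (BMU) by squared Euclidean distance, then moves every codebook vector
#' toward the neighbourhood-weighted mean of the genes, with a Gaussian (or
#' bubble) kernel over the wrapped grid distance. Radius and learning rate
#' decay linearly to (1, lr0/100). The codebook is initialised by sampling
#' genes, so training is deterministic for a fixed seed.
#'
#' @param X gene x sample matrix, genes standardised.
#' @param grid a [som_grid()].
#' @param epochs training epochs.
#' @param lr0 initial learning rate.
#' @param radius0 initial neighbourhood radius; default half the larger grid
#'   dimension.
#' @param seed integer seed.
#' @param strict error (instead of warn) when the grid has more nodes than
#'   there are genes.
#' @return A list of class `som_model`: `grid`, `codebook` (node x sample),
#'   `qe_trace` (per-epoch quantisation error), `trace` (schedules, seed).
#' @export
train_som <- function(X, grid = som_grid(), epochs = 100, lr0 = 0.5,
                      radius0 = max(grid$rows, grid$cols) / 2, seed = 1L,
                      strict = FALSE) {
  X <- as_values(X)
  if (anyNA(X)) stop("missing values in X; impute first")
  n_nodes <- grid$rows * grid$cols
  if (nrow(X) < n_nodes) {
    msg <- sprintf("grid has %d nodes but only %d genes", n_nodes, nrow(X))
    if (strict) stop(msg) else warning(msg)
  }
  set.seed(stage_seed(seed, "som"))
  init <- sample.int(nrow(X), n_nodes, replace = nrow(X) < n_nodes)
  codebook <- X[init, , drop = FALSE]
  rownames(codebook) <- sprintf("node_%03d", seq_len(n_nodes))
  G <- grid_distance_matrix(grid)
  # radius decays linearly to 1; a start at or below 1 stays constant
  radius_at <- function(e) if (epochs == 1 || radius0 <= 1) radius0 else
    radius0 + (1 - radius0) * (e - 1) / (epochs - 1)
  lr_at <- function(e) if (epochs == 1) lr0 else
    lr0 + (lr0 / 100 - lr0) * (e - 1) / (epochs - 1)
  qe_trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    bmu <- bmu_of(X, codebook)
    qe_trace[e] <- mean(rowSums((X - codebook[bmu, , drop = FALSE])^2))
    r <- max(radius_at(e), 1e-8)
    H <- if (grid$neighbourhood == "gaussian")
      exp(-G^2 / (2 * r^2)) else (G <= r) * 1
    W <- H[, bmu, drop = FALSE]            # node x gene kernel weights
    wsum <- rowSums(W)
    target <- (W %*% X)
    upd <- wsum > 0
    target[upd, ] <- target[upd, , drop = FALSE] / wsum[upd]
    target[!upd, ] <- codebook[!upd, , drop = FALSE]
    codebook <- codebook + lr_at(e) * (target - codebook)
  }
  structure(list(grid = grid, codebook = codebook,
                 distance = "squared_euclidean", qe_trace = qe_trace,
                 trace = list(epochs = epochs, lr0 = lr0, radius0 = radius0,
                              seed = seed)),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %dx%d %s grid, %d-dim codebook, final QE %.4g\n",
              x$grid$rows, x$grid$cols, x$grid$topology, ncol(x$codebook),
              x$qe_trace[length(x$qe_trace)]))
  invisible(x)
}

#' SOM quality metrics
#'
#' Explained clustering variance `1 - sum ||x - codebook(BMU)||^2 /
#' sum ||x - mean||^2` (defined as 1 when total variance is zero), topology
#' error (fraction of genes whose first and second BMUs are not grid
#' neighbours at wrapped distance 1), and neighbourhood preservation (mean
#' Spearman correlation, over genes, between feature-space distances and BMU
#' grid distances to a seeded random probe subset).
#'
#' @param model a trained [train_som()] model.
#' @param X gene x sample matrix to evaluate (training or holdout genes).
#' @param n_probes probe-subset size for neighbourhood preservation.
#' @param seed seed for the probe draw.
#' @return List with `explained_clustering_variance`, `topology_error`,
#'   `neighbourhood_preservation`.
#' @export
som_quality <- function(model, X, n_probes = 100, seed = 1L) {
  X <- as_values(X)
  if (!nrow(X)) stop("empty evaluation set")
  bmu2 <- bmu_of(X, model$codebook, second = TRUE)
  qerr <- sum(rowSums((X - model$codebook[bmu2[, 1], , drop = FALSE])^2))
  tot <- sum(sweep(X, 2, colMeans(X), "-")^2)
  ecv <- if (tot == 0) 1 else 1 - qerr / tot
  te <- mean(toroidal_distance(model$grid, bmu2[, 1], bmu2[, 2]) != 1)
  set.seed(stage_seed(seed, "som_quality"))
  probes <- sample.int(nrow(X), min(n_probes, nrow(X)))
  G <- grid_distance_matrix(model$grid)
  np <- vapply(seq_len(nrow(X)), function(i) {
    pr <- setdiff(probes, i)
    if (length(pr) < 3) return(NA_real_)
    dfeat <- sqrt(colSums((t(X[pr, , drop = FALSE]) - X[i, ])^2))
    dgrid <- G[bmu2[i, 1], bmu2[pr, 1]]
    if (stats::sd(dfeat) == 0 || stats::sd(dgrid) == 0) return(0)
    stats::cor(dfeat, dgrid, method = "spearman")
  }, numeric(1))
  list(explained_clustering_variance = ecv, topology_error = te,
       neighbourhood_preservation = mean(np, na.rm = TRUE))
}

#' Extract metagenes (gene micro-clusters) from a trained SOM
#'
#' Genes map to their BMU; ties break to the lower node index. Empty nodes
#' are retained as empty metagenes but excluded from the scorable sets.
#'
#' @param model a [train_som()] model.
#' @param X the gene x sample matrix the genes live in.
#' @return List of class `metagene_set`: `sets` (non-empty node -> gene ids),
#'   `assignment` (gene -> node index), `n_nodes`, `empty_nodes`.
#' @export
extract_metagenes <- function(model, X) {
  X <- as_values(X)
  bmu <- bmu_of(X, model$codebook)
  names(bmu) <- rownames(X)
  n_nodes <- nrow(model$codebook)
  sets <- split(rownames(X), factor(bmu, levels = seq_len(n_nodes)))
  names(sets) <- rownames(model$codebook)
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    message(length(empty), " empty SOM node(s) excluded from scorable metagenes")
  structure(list(sets = sets[lengths(sets) > 0], assignment = bmu,
                 n_nodes = n_nodes, empty_nodes = empty),
            class = "metagene_set")
}

#' @export
print.metagene_set <- function(x, ...) {
  cat(sprintf("<metagene_set> %d scorable metagenes over %d genes (%d empty nodes)\n",
              length(x$sets), length(x$assignment), length(x$empty_nodes)))
  invisible(x)
}
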