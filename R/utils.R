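#' Derive a stage-specific random seed
#'
#' Stage seeds are pure functions of the global seed and the stage name, so
#' changing one stage's parameters never perturbs another stage's randomness.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

## Column-wise z-scoring with reusable parameters (sample x feature matrices).
standardise_cols <- function(S, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(S)
  if (is.null(scale)) {
    scale <- apply(S, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  Z <- sweep(sweep(S, 2, center, "-"), 2, scale, "/")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  Z
}

## Row-wise (per gene) z-scoring for gene x sample matrices.
standardise_rows <- function(X) {
  m <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  s[s == 0] <- 1
  (X - m) / s
}

#' Rand index and adjusted Rand index between two label vectors
#'
#' Used for cross-validated cluster stability and recovery of simulated truth.
#'
#' @param a,b label vectors of equal length.
#' @return `rand_index()` the plain Rand index; `adjusted_rand()` the
#'   chance-corrected (Hubert-Arabie) version.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  agree <- sum_comb(tab)
  total <- choose(n, 2)
  ra <- sum_comb(rowSums(tab)); cb <- sum_comb(colSums(tab))
  (total + 2 * agree - ra - cb) / total
}

#' @rdname rand_index
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  ra <- sum_comb(rowSums(tab)); cb <- sum_comb(colSums(tab))
  expected <- ra * cb / choose(n, 2)
  maxidx <- (ra + cb) / 2
  if (maxidx == expected) return(1)
  (idx - expected) / (maxidx - expected)
}

## Mean silhouette width; delegates to the cluster package.
mean_silhouette <- function(labels, S) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("silhouette needs >= 2 clusters")
  sil <- cluster::silhouette(labels, stats::dist(S))
  mean(sil[, "sil_width"])
}

## Content hash of an arbitrary R object (run-manifest bookkeeping).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
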