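#' Cohort-stratified permutation test of mutation enrichment in clusters
#'
#' The observed statistic for a (gene, cluster) pair is the weighted mutation
#' frequency within the cluster. The null permutes cluster labels within each
#' cohort (preserving per-cohort cluster sizes); the one-sided add-one
#' corrected p-value is the fraction of permutations reaching the observed
#' frequency. Enrichment ratio is observed over the permutation mean.
#' Benjamini-Hochberg FDR is applied across all (gene, cluster) pairs.
#'
#' @param mut binary gene x sample mutation matrix.
#' @param assignment cluster labels (named by sample) or
#'   `cluster_assignment`.
#' @param cohort optional per-sample cohort ids (single stratum when absent).
#' @param n_perm number of permutations (>= 100).
#' @param weights optional per-sample weights (default 1).
#' @param seed integer seed.
#' @param depletion also test the lower tail.
#' @return `data.frame` per (gene, cluster): observed and expected frequency,
#'   enrichment ratio, permutation p, FDR q (and depletion columns when
#'   requested).
#' @export
permutation_enrichment <- function(mut, assignment, cohort = NULL,
                                   n_perm = 1000, weights = NULL, seed = 1L,
                                   depletion = FALSE) {
  mut <- as.matrix(mut)
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  if (!is.null(names(labels))) {
    if (!all(colnames(mut) %in% names(labels)))
      stop("assignment does not cover all mutation samples")
    labels <- labels[colnames(mut)]
  }
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- ncol(mut)
  if (is.null(cohort)) cohort <- rep("all", n)
  if (is.null(weights)) weights <- rep(1, n)
  cl <- sort(unique(labels))
  if (any(table(factor(labels, levels = cl)) == 0)) stop("empty cluster")
  strata <- split(seq_len(n), cohort)

  wfreq <- function(lab) {
    # weighted mutation frequency per gene x cluster
    vapply(cl, function(c) {
      idx <- lab == c
      drop(mut[, idx, drop = FALSE] %*% weights[idx]) / sum(weights[idx])
    }, numeric(nrow(mut)))
  }
  obs <- matrix(wfreq(labels), nrow = nrow(mut))
  set.seed(stage_seed(seed, "mut_enrichment"))
  count_ge <- matrix(0, nrow(mut), length(cl))
  count_le <- matrix(0, nrow(mut), length(cl))
  acc <- matrix(0, nrow(mut), length(cl))
  for (b in seq_len(n_perm)) {
    lab_p <- labels
    for (s in strata) lab_p[s] <- labels[s][sample.int(length(s))]
    f <- matrix(wfreq(lab_p), nrow = nrow(mut))
    count_ge <- count_ge + (f >= obs)
    count_le <- count_le + (f <= obs)
    acc <- acc + f
  }
  expected <- acc / n_perm
  p <- (1 + count_ge) / (n_perm + 1)
  out <- data.frame(
    gene = rep(rownames(mut), times = length(cl)),
    cluster = rep(cl, each = nrow(mut)),
    observed = as.vector(obs), expected = as.vector(expected),
    enrichment_ratio = as.vector(ifelse(expected > 0, obs / expected, NA)),
    p = as.vector(p), row.names = NULL)
  out$q <- stats::p.adjust(out$p, "BH")
  if (depletion) {
    out$p_depletion <- as.vector((1 + count_le) / (n_perm + 1))
    out$q_depletion <- stats::p.adjust(out$p_depletion, "BH")
  }
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Weighted per-gene per-cluster mutation percentages
#'
#' Plain oncoplot-style frequency table.
#'
#' @inheritParams permutation_enrichment
#' @return Gene x cluster matrix of percentages (0-100).
#' @export
frequency_table <- function(mut, assignment, weights = NULL) {
  mut <- as.matrix(mut)
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  if (!is.null(names(labels))) labels <- labels[colnames(mut)]
  if (is.null(weights)) weights <- rep(1, ncol(mut))
  cl <- sort(unique(labels))
  out <- vapply(cl, function(c) {
    idx <- labels == c
    100 * drop(mut[, idx, drop = FALSE] %*% weights[idx]) / sum(weights[idx])
  }, numeric(nrow(mut)))
  out <- matrix(out, nrow = nrow(mut),
                dimnames = list(rownames(mut), paste0("cluster_", cl)))
  out
}
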