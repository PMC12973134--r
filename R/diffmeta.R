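#' Composite differential-regulation caller
#'
#' Per feature, a one-way ANOVA across clusters with the eta-squared effect
#' size (between-cluster over total sum of squares); per (feature, cluster),
#' a one-sample T-test of the cluster's values against the fixed cohort grand
#' mean, with the mean log2 difference as the effect estimate. Benjamini-
#' Hochberg FDR is applied separately to the ANOVA p family and to the pooled
#' T-test p family. A (feature, cluster) pair is flagged differentially
#' regulated when `q_anova < q_max`, `eta2 >= eta2_min` and `q_t < q_max` --
#' the composite rule used throughout the cluster characterisation.
#'
#' @param X [expression_matrix()] or matrix, features x samples.
#' @param assignment `cluster_assignment` or named integer labels covering
#'   the samples of `X`.
#' @param eta2_min minimum eta-squared.
#' @param q_max FDR threshold for both test families.
#' @param welch use Welch's unequal-variance ANOVA instead of the classic
#'   equal-variance decomposition (the eta2 reported is unchanged).
#' @return Object of class `diff_result`: `anova` (feature table with p, q,
#'   eta2) and `clusters` (per feature x cluster: log2 difference vs cohort
#'   mean, t, p, q, se, flag).
#' @export
diff_features <- function(X, assignment, eta2_min = 0.06, q_max = 0.05,
                          welch = FALSE) {
  values <- as_values(X)
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  labels <- labels[colnames(values)]
  if (anyNA(labels)) stop("assignment does not cover all samples")
  cl <- sort(unique(labels))
  if (length(cl) < 2 || min(table(labels)) < 3)
    stop("need >= 2 clusters with >= 3 samples each")
  groups <- lapply(cl, function(c) which(labels == c))
  nc <- lengths(groups)
  n <- ncol(values)
  keep <- apply(values, 1, stats::sd) > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance feature(s) skipped")
  V <- values[keep, , drop = FALSE]

  gm <- rowMeans(V)
  means <- matrix(vapply(groups, function(g) rowMeans(V[, g, drop = FALSE]),
                         numeric(nrow(V))), nrow = nrow(V))
  vars <- matrix(vapply(groups, function(g)
    apply(V[, g, drop = FALSE], 1, stats::var), numeric(nrow(V))),
    nrow = nrow(V))
  ss_total <- apply(V, 1, function(x) sum((x - mean(x))^2))
  ss_between <- rowSums(sweep((means - gm)^2, 2, nc, "*"))
  eta2 <- ss_between / ss_total
  if (welch) {
    wj <- sweep(1 / vars, 2, nc, "*")          # n_j / s_j^2
    wsum <- rowSums(wj)
    mw <- rowSums(wj * means) / wsum
    A <- rowSums(wj * (means - mw)^2) / (length(cl) - 1)
    B <- 1 + 2 * (length(cl) - 2) / (length(cl)^2 - 1) *
      rowSums(sweep((1 - wj / wsum)^2, 2, nc - 1, "/"))
    Fstat <- A / B
    df2 <- (length(cl)^2 - 1) /
      (3 * rowSums(sweep((1 - wj / wsum)^2, 2, nc - 1, "/")))
    p_anova <- stats::pf(Fstat, length(cl) - 1, df2, lower.tail = FALSE)
  } else {
    df1 <- length(cl) - 1
    df2 <- n - length(cl)
    Fstat <- (ss_between / df1) / ((ss_total - ss_between) / df2)
    p_anova <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  q_anova <- stats::p.adjust(p_anova, "BH")

  sds <- sqrt(vars)
  tstat <- (means - gm) / (sds / sqrt(matrix(nc, nrow(V), length(cl), byrow = TRUE)))
  p_t <- 2 * stats::pt(abs(tstat), df = matrix(nc - 1, nrow(V), length(cl),
                                               byrow = TRUE), lower.tail = FALSE)
  q_t <- matrix(stats::p.adjust(p_t, "BH"), nrow(V))
  flag <- (q_anova < q_max) & (eta2 >= eta2_min) & (q_t < q_max)

  anova_tab <- data.frame(feature = rownames(V), F = Fstat, p = p_anova,
                          q = q_anova, eta2 = eta2, row.names = NULL)
  cluster_tab <- data.frame(
    feature = rep(rownames(V), times = length(cl)),
    cluster = rep(cl, each = nrow(V)),
    log2_diff = as.vector(means - gm),
    se = as.vector(sds / sqrt(matrix(nc, nrow(V), length(cl), byrow = TRUE))),
    t = as.vector(tstat), p = as.vector(p_t), q = as.vector(q_t),
    flag = as.vector(flag), row.names = NULL)
  structure(list(anova = anova_tab, clusters = cluster_tab,
                 eta2_min = eta2_min, q_max = q_max),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("<diff_result> %d features; %d flagged (feature, cluster) pairs\n",
              nrow(x$anova), sum(x$clusters$flag)))
  invisible(x)
}

#' Features differentially regulated in multiple cohorts
#'
#' A feature is kept for a cluster when it is flagged in at least
#' `min_cohorts` cohorts; with `direction_consistent = TRUE` the sign of its
#' log2 difference must agree across all flagging cohorts.
#'
#' @param results_by_cohort named list of [diff_features()] results.
#' @param min_cohorts minimum number of flagging cohorts.
#' @param direction_consistent require a common sign.
#' @return Named list (per cluster) of character feature vectors.
#' @export
shared_features <- function(results_by_cohort, min_cohorts,
                            direction_consistent = TRUE) {
  if (min_cohorts > length(results_by_cohort))
    stop("min_cohorts exceeds the number of cohorts")
  tabs <- lapply(results_by_cohort, function(r) {
    d <- r$clusters[r$clusters$flag, c("feature", "cluster", "log2_diff")]
    d
  })
  all_flags <- do.call(rbind, tabs)
  if (is.null(all_flags) || !nrow(all_flags)) return(list())
  out <- lapply(sort(unique(all_flags$cluster)), function(cl) {
    d <- all_flags[all_flags$cluster == cl, ]
    counts <- table(d$feature)
    keep <- names(counts)[counts >= min_cohorts]
    if (direction_consistent && length(keep)) {
      consistent <- vapply(keep, function(f) {
        s <- sign(d$log2_diff[d$feature == f])
        all(s == s[1])
      }, logical(1))
      keep <- keep[consistent]
    }
    sort(keep)
  })
  names(out) <- paste0("cluster_", sort(unique(all_flags$cluster)))
  out
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments pooling of per-cohort estimates: fixed weights
#' `w = 1/se^2`, heterogeneity `Q = sum w (y - ybar_w)^2`, between-study
#' variance `tau2 = max(0, (Q - (n-1)) / (sum w - sum w^2 / sum w))`, pooled
#' estimate with weights `1 / (se^2 + tau2)` and its normal 95% CI.
#'
#' @param estimates per-study effect estimates (e.g. log2 differences).
#' @param ses per-study standard errors (> 0).
#' @return List of class `meta_estimate`: `estimate`, `se`, `ci` (length 2),
#'   `tau2`, `Q`, `n_studies`.
#' @export
dl_meta <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses))
  if (any(ses <= 0)) stop("standard errors must be positive")
  n <- length(estimates)
  if (n < 2) {
    warning("single study: returning the input estimate with tau2 = 0")
    est <- estimates[1]; se <- ses[1]
    return(structure(list(estimate = est, se = se,
                          ci = est + c(-1, 1) * 1.96 * se, tau2 = 0,
                          Q = 0, n_studies = 1L), class = "meta_estimate"))
  }
  w <- 1 / ses^2
  ybar <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - ybar)^2)
  tau2 <- max(0, (Q - (n - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wstar <- 1 / (ses^2 + tau2)
  est <- sum(wstar * estimates) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  structure(list(estimate = est, se = se, ci = est + c(-1, 1) * 1.96 * se,
                 tau2 = tau2, Q = Q, n_studies = n), class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("<meta_estimate> %.4g [%.4g, %.4g], tau2=%.4g, Q=%.4g, n=%d\n",
              x$estimate, x$ci[1], x$ci[2], x$tau2, x$Q, x$n_studies))
  invisible(x)
}

#' ROC-based marker selection per cluster
#'
#' For every feature and cluster, the cluster-vs-rest AUC computed from the
#' Mann-Whitney U statistic with mid-ranks for ties; features with
#' `AUC >= auc_min` are markers. Constant features score 0.5 by convention.
#'
#' @param X [expression_matrix()] or matrix, features x samples.
#' @param assignment cluster labels (named) or `cluster_assignment`.
#' @param auc_min marker threshold.
#' @return `data.frame` feature x cluster with `auc` and `marker` flag.
#' @export
marker_auc <- function(X, assignment, auc_min = 0.714) {
  values <- as_values(X)
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  labels <- labels[colnames(values)]
  cl <- sort(unique(labels))
  rows <- lapply(cl, function(c) {
    pos <- labels == c
    n1 <- sum(pos); n2 <- sum(!pos)
    if (n1 == 0 || n2 == 0) stop("one-vs-rest group empty for cluster ", c)
    auc <- apply(values, 1, function(x) {
      if (stats::sd(x) == 0) return(0.5)
      r <- rank(x)
      (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    })
    data.frame(feature = rownames(values), cluster = c, auc = auc,
               marker = auc >= auc_min, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Universal markers across modalities
#'
#' @param marker_tables list of [marker_auc()] outputs (one per modality).
#' @return Named list per cluster: features that are markers in every
#'   supplied modality.
#' @export
universal_markers <- function(marker_tables) {
  cl <- sort(unique(unlist(lapply(marker_tables, function(t) t$cluster))))
  out <- lapply(cl, function(c) {
    sets <- lapply(marker_tables, function(t)
      t$feature[t$cluster == c & t$marker])
    sort(Reduce(intersect, sets))
  })
  names(out) <- paste0("cluster_", cl)
  out
}
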