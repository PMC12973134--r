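## k-means++ seeding on the full feature set; ties and draws are seeded by
## the caller's RNG state.
kmeanspp_init <- function(S, k) {
  n <- nrow(S)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((S - matrix(S[centers[1], ], n, ncol(S), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = prob)
    d2_new <- rowSums((S - matrix(S[centers[j + 1], ], n, ncol(S), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  S[centers, , drop = FALSE]
}

## Squared Euclidean distances of samples to centroids over given columns.
dist_to_centroids <- function(S, centroids, cols = seq_len(ncol(S))) {
  Sa <- S[, cols, drop = FALSE]
  Ca <- centroids[, cols, drop = FALSE]
  d2 <- outer(rowSums(Sa^2), rowSums(Ca^2), "+") - 2 * Sa %*% t(Ca)
  pmax(d2, 0)
}

#' Hard-threshold regularised k-means over metagene scores
#'
#' k-means with per-feature hard-threshold shrinkage: after each assignment
#' and mean update, any feature whose between-cluster sum of squares does not
#' exceed `lambda * n` is deactivated -- its centroid entries collapse to the
#' global feature mean and it stops contributing to assignments. Features
#' whose separation grows again may re-enter. The penalised objective,
#'
#' `sum_(j active) WCSS_j + sum_(j inactive) TSS_j + lambda * n * #active`,
#'
#' decreases monotonically: assignment, mean update and thresholding are each
#' coordinate-descent steps on it. `lambda = 0` reduces exactly to Lloyd
#' k-means. Best of `n_init` k-means++ restarts is kept.
#'
#' @param S sample x feature score matrix.
#' @param k number of clusters.
#' @param lambda shrinkage parameter (>= 0).
#' @param n_init number of seeded restarts.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @param standardise z-score features first (scaling stored in the model and
#'   reused by [predict_htk()]). Set `FALSE` when `S` is already standardised.
#' @return Object of class `htk_model`: centroids (k x feature),
#'   `active_features`, `global_means`, `assignments`, `objective`,
#'   `objective_trace` of the winning restart, and the training scaling.
#' @export
fit_htkmeans <- function(S, k = 3, lambda = 0, n_init = 50, max_iter = 100,
                         seed = 1L, standardise = TRUE) {
  S <- as.matrix(S)
  if (nrow(S) < k) stop("fewer samples than clusters")
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(rownames(S))) rownames(S) <- sprintf("s%04d", seq_len(nrow(S)))
  center <- if (standardise) colMeans(S) else rep(0, ncol(S))
  scl <- if (standardise) {
    s <- apply(S, 2, stats::sd); s[s == 0] <- 1; s
  } else rep(1, ncol(S))
  Z <- sweep(sweep(S, 2, center, "-"), 2, scl, "/")
  n <- nrow(Z); p <- ncol(Z)
  gm <- colMeans(Z)
  tss_j <- colSums(sweep(Z, 2, gm, "-")^2)

  set.seed(stage_seed(seed, "htkmeans"))
  best <- NULL
  for (init in seq_len(n_init)) {
    centroids <- kmeanspp_init(Z, k)
    active <- rep(TRUE, p)
    assign_prev <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      full_cent <- matrix(gm, k, p, byrow = TRUE)
      full_cent[, active] <- centroids[, active, drop = FALSE]
      d2 <- dist_to_centroids(Z, full_cent, which(active))
      asg <- max.col(-d2, ties.method = "first")
      # re-seed empty clusters at the farthest (not yet used) samples
      reseeded <- integer(0)
      for (c in which(tabulate(asg, k) == 0)) {
        d_assigned <- d2[cbind(seq_len(n), asg)]
        d_assigned[reseeded] <- -Inf
        far <- which.max(d_assigned)
        full_cent[c, ] <- Z[far, ]
        asg[far] <- c
        reseeded <- c(reseeded, far)
      }
      cent_new <- rowsum(Z, asg)[as.character(seq_len(k)), , drop = FALSE] /
        tabulate(asg, k)
      bcss_j <- colSums(tabulate(asg, k) *
                          sweep(cent_new, 2, gm, "-")^2)
      active <- bcss_j > lambda * n
      centroids <- cent_new
      wcss_active <- sum(tss_j[active]) - sum(bcss_j[active])
      obj <- wcss_active + sum(tss_j[!active]) + lambda * n * sum(active)
      trace <- c(trace, obj)
      if (identical(asg, assign_prev)) break
      assign_prev <- asg
    }
    if (!any(active)) next  # fully shrunk restart carries no usable model
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(assignments = asg, centroids = centroids, active = active,
                   objective = obj, trace = trace)
    }
  }
  if (is.null(best))
    stop("fully shrunk model: no feature separates the clusters at this lambda")
  centroids <- matrix(gm, k, p, byrow = TRUE,
                      dimnames = list(paste0("cluster_", seq_len(k)), colnames(S)))
  centroids[, best$active] <- best$centroids[, best$active, drop = FALSE]
  structure(list(k = k, lambda = lambda, centroids = centroids,
                 active_features = stats::setNames(best$active, colnames(S)),
                 global_means = stats::setNames(gm, colnames(S)),
                 assignments = stats::setNames(best$assignments, rownames(S)),
                 objective = best$objective, objective_trace = best$trace,
                 scaling = list(center = center, scale = scl),
                 seed = seed, n_init = n_init),
            class = "htk_model")
}

#' @export
print.htk_model <- function(x, ...) {
  cat(sprintf("<htk_model> k=%d lambda=%.4g: %d/%d active features, objective %.4g\n",
              x$k, x$lambda, sum(x$active_features), length(x$active_features),
              x$objective))
  invisible(x)
}

#' Assign new samples to fitted HTK clusters
#'
#' New samples are standardised with the model's training parameters and
#' assigned to the nearest centroid over the active features; ties break to
#' the lower cluster index.
#'
#' @param model an [fit_htkmeans()] model.
#' @param S_new sample x feature matrix carrying the model's features.
#' @return List of class `cluster_assignment`: `labels`, `distance` (sample x
#'   cluster squared distances over active features), `provenance`.
#' @export
predict_htk <- function(model, S_new) {
  S_new <- as.matrix(S_new)
  miss <- setdiff(names(model$active_features), colnames(S_new))
  if (length(miss)) stop("missing model features: ", paste(head(miss, 5), collapse = ", "))
  S_new <- S_new[, names(model$active_features), drop = FALSE]
  Z <- sweep(sweep(S_new, 2, model$scaling$center, "-"), 2,
             model$scaling$scale, "/")
  d2 <- dist_to_centroids(Z, model$centroids, which(model$active_features))
  labels <- max.col(-d2, ties.method = "first")
  structure(list(labels = stats::setNames(labels, rownames(S_new)),
                 distance = d2, provenance = "htk"),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> (%s) %d samples: %s\n", x$provenance,
              length(x$labels),
              paste(sprintf("c%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Grid search for the HTK cluster count and shrinkage parameter
#'
#' For every (k, lambda) candidate: mean silhouette width, explained
#' clustering variance over active features, neighbourhood preservation
#' (Spearman correlation between sample-sample distances and the distances of
#' their assigned centroids), and cross-validated label stability (fold-out
#' samples assigned by [predict_htk()] from a fit on the remaining folds,
#' compared with the full-data labels by Rand index). Candidates are ranked by
#' the summed rank of the four criteria (higher is better for each).
#'
#' @param S sample x feature score matrix.
#' @param k_grid,lambda_grid candidate values.
#' @param folds cross-validation folds.
#' @param n_init restarts per fit (smaller than the final fit for speed).
#' @param seed integer seed.
#' @return `data.frame` sorted best-first with the four criteria and rank sum.
#' @export
tune_htkmeans <- function(S, k_grid = 2:6, lambda_grid = c(0, 0.01, 0.05),
                          folds = 5, n_init = 10, seed = 1L) {
  if (!length(k_grid) || !length(lambda_grid)) stop("empty tuning grid")
  S <- as.matrix(S)
  n <- nrow(S)
  set.seed(stage_seed(seed, "htk_tune"))
  fold_of <- sample(rep_len(seq_len(folds), n))
  if (min(table(fold_of)) < max(k_grid)) stop("fold with fewer samples than k")
  grid <- expand.grid(k = k_grid, lambda = lambda_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    k <- grid$k[i]; lambda <- grid$lambda[i]
    fit <- tryCatch(fit_htkmeans(S, k, lambda, n_init = n_init, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    q <- clustering_quality(fit, S)
    stab <- mean(vapply(seq_len(folds), function(f) {
      tr <- fold_of != f
      fit_f <- fit_htkmeans(S[tr, , drop = FALSE], k, lambda,
                            n_init = n_init, seed = seed)
      pred <- predict_htk(fit_f, S[!tr, , drop = FALSE])
      rand_index(pred$labels, fit$assignments[!tr])
    }, numeric(1)))
    data.frame(k = k, lambda = lambda, silhouette = q$silhouette,
               explained_variance = q$explained_variance,
               neighbourhood_preservation = q$neighbourhood_preservation,
               cv_stability = stab, active_features = sum(fit$active_features))
  })
  tab <- do.call(rbind, rows)
  crit <- c("silhouette", "explained_variance",
            "neighbourhood_preservation", "cv_stability")
  tab$rank_sum <- rowSums(vapply(crit, function(cc) rank(tab[[cc]]),
                                 numeric(nrow(tab))))
  tab[order(-tab$rank_sum), ]
}

#' Internal quality metrics of a fitted clustering
#'
#' @param model an `htk_model` (or a list with `assignments`, `centroids`,
#'   `active_features`, `scaling`).
#' @param S the sample x feature matrix the model was fitted on.
#' @param max_pairs subsample cap for the neighbourhood-preservation
#'   correlation.
#' @return List: `silhouette`, `explained_variance`,
#'   `neighbourhood_preservation`, `intercluster_distance` (squared Euclidean
#'   between centroids over active features).
#' @export
clustering_quality <- function(model, S, max_pairs = 200) {
  S <- as.matrix(S)
  Z <- sweep(sweep(S, 2, model$scaling$center, "-"), 2, model$scaling$scale, "/")
  act <- which(model$active_features)
  labels <- model$assignments
  if (length(unique(labels)) < 2) stop("silhouette undefined for < 2 clusters")
  if (all(table(labels) == 1)) stop("silhouette undefined for singleton-only clustering")
  Za <- Z[, act, drop = FALSE]
  sil <- mean_silhouette(labels, Za)
  cent <- model$centroids[, act, drop = FALSE]
  wcss <- sum((Za - cent[labels, , drop = FALSE])^2)
  tss <- sum(sweep(Za, 2, colMeans(Za), "-")^2)
  ecv <- if (tss == 0) 1 else 1 - wcss / tss
  idx <- seq_len(min(nrow(Za), max_pairs))
  dsample <- as.vector(stats::dist(Za[idx, , drop = FALSE]))
  cdist_mat <- as.matrix(stats::dist(cent))
  dcent <- as.vector(stats::as.dist(cdist_mat[labels[idx], labels[idx]]))
  np <- if (stats::sd(dcent) == 0 || stats::sd(dsample) == 0) 0 else
    stats::cor(dsample, dcent, method = "spearman")
  inter <- as.matrix(stats::dist(cent))^2
  list(silhouette = sil, explained_variance = ecv,
       neighbourhood_preservation = np, intercluster_distance = inter)
}
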