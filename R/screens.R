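#' Bootstrap analysis of CRISPR knockout effects per cluster
#'
#' Chronos scores arrive sign-flipped (positive = growth inhibition). For
#' each (gene, cluster), cell lines are resampled within the cluster to give
#' the bootstrap mean and percentile 95% CI; a biologically relevant effect
#' is flagged when the observed mean exceeds `effect_min`. Pairwise
#' between-cluster differences get an add-one-corrected two-sided bootstrap
#' p-value from the resampled difference distribution.
#'
#' @param chronos cell line x gene score matrix.
#' @param labels integer cluster labels per line (named).
#' @param n_boot bootstrap replicates.
#' @param effect_min effect threshold on the mean score.
#' @param seed integer seed.
#' @return List: `effects` (gene x cluster table with mean, CI, flag) and
#'   `differences` (gene x cluster-pair table with difference and p).
#' @export
chronos_bootstrap <- function(chronos, labels, n_boot = 2000, effect_min = 0.5,
                              seed = 1L) {
  chronos <- as.matrix(chronos)
  if (!is.null(names(labels))) labels <- labels[rownames(chronos)]
  stopifnot(length(labels) == nrow(chronos))
  counts <- table(labels)
  drop_cl <- as.integer(names(counts)[counts < 2])
  if (length(drop_cl))
    warning("cluster(s) with a single cell line excluded: ",
            paste(drop_cl, collapse = ", "))
  cl <- setdiff(sort(unique(labels)), drop_cl)
  if (length(cl) < 1) stop("no cluster with >= 2 cell lines")
  set.seed(stage_seed(seed, "chronos_boot"))
  boot_means <- list()
  eff_rows <- list()
  for (c in cl) {
    idx <- which(labels == c)
    bm <- vapply(seq_len(n_boot), function(b) {
      colMeans(chronos[sample(idx, replace = TRUE), , drop = FALSE])
    }, numeric(ncol(chronos)))
    bm <- matrix(bm, nrow = ncol(chronos))       # gene x boot
    boot_means[[as.character(c)]] <- bm
    obs <- colMeans(chronos[idx, , drop = FALSE])
    ci <- apply(bm, 1, stats::quantile, probs = c(0.025, 0.975))
    eff_rows[[as.character(c)]] <- data.frame(
      gene = colnames(chronos), cluster = c, mean = obs,
      lower = ci[1, ], upper = ci[2, ], effect = obs > effect_min,
      row.names = NULL)
  }
  effects <- do.call(rbind, eff_rows)
  diffs <- list()
  if (length(cl) >= 2) {
    pairs <- utils::combn(cl, 2)
    for (pp in seq_len(ncol(pairs))) {
      a <- pairs[1, pp]; b <- pairs[2, pp]
      dd <- boot_means[[as.character(a)]] - boot_means[[as.character(b)]]
      obs_d <- colMeans(chronos[labels == a, , drop = FALSE]) -
        colMeans(chronos[labels == b, , drop = FALSE])
      opp <- ifelse(obs_d >= 0, rowSums(dd < 0), rowSums(dd > 0))
      p <- pmin(1, 2 * (1 + opp) / (n_boot + 1))
      diffs[[pp]] <- data.frame(gene = colnames(chronos), cluster_a = a,
                                cluster_b = b, difference = obs_d, p = p,
                                row.names = NULL)
    }
  }
  list(effects = effects,
       differences = if (length(diffs)) do.call(rbind, diffs) else NULL)
}

#' Train ridge drug-response models on cell-line expression
#'
#' Per drug, genes are standardised on the training lines, the penalty is
#' chosen by k-fold cross-validated MSE over `lambda_grid`, and coefficients
#' come from the closed-form ridge solution
#' `(X'X + lambda * I)^-1 X'y` on centred data (intercept unpenalised).
#' At `lambda = 0` this is ordinary least squares.
#'
#' @param train_expr cell line x gene matrix.
#' @param response cell line x drug matrix (or vector for one drug).
#' @param lambda_grid candidate penalties.
#' @param folds CV folds.
#' @param seed integer seed.
#' @return List of class `drug_model_set`: per drug coefficients, intercept,
#'   chosen lambda, and the feature scaling.
#' @export
ridge_train <- function(train_expr, response, lambda_grid = 10^seq(-2, 3, by = 0.5),
                        folds = 5, seed = 1L) {
  X <- as.matrix(train_expr)
  R <- as.matrix(response)
  if (is.null(colnames(R))) colnames(R) <- sprintf("drug_%02d", seq_len(ncol(R)))
  stopifnot(nrow(X) == nrow(R))
  Z <- standardise_cols(X)
  center <- attr(Z, "center"); scl <- attr(Z, "scale")
  set.seed(stage_seed(seed, "ridge"))
  fold_of <- sample(rep_len(seq_len(folds), nrow(X)))
  solve_ridge <- function(Zt, yt, lambda) {
    p <- ncol(Zt)
    A <- crossprod(Zt) + diag(lambda, p)
    drop(solve(A, crossprod(Zt, yt)))
  }
  models <- lapply(colnames(R), function(d) {
    y <- R[, d]
    if (stats::sd(y) == 0) {
      warning("constant response for ", d, "; model skipped")
      return(NULL)
    }
    ybar <- mean(y)
    cv_mse <- vapply(lambda_grid, function(lm_) {
      mean(vapply(seq_len(folds), function(f) {
        tr <- fold_of != f
        beta <- solve_ridge(Z[tr, , drop = FALSE], y[tr] - mean(y[tr]), lm_)
        pred <- mean(y[tr]) + drop(Z[!tr, , drop = FALSE] %*% beta)
        mean((y[!tr] - pred)^2)
      }, numeric(1)))
    }, numeric(1))
    lambda <- lambda_grid[which.min(cv_mse)]
    beta <- solve_ridge(Z, y - ybar, lambda)
    list(coefficients = stats::setNames(beta, colnames(X)), intercept = ybar,
         lambda = lambda, cv_mse = stats::setNames(cv_mse, lambda_grid))
  })
  names(models) <- colnames(R)
  structure(list(models = Filter(Negate(is.null), models),
                 center = center, scale = scl, features = colnames(X)),
            class = "drug_model_set")
}

#' Predict drug resistance for bulk samples and Z-score within cohort
#'
#' Samples are scaled with the training parameters; model genes missing from
#' the bulk data (up to 50%) are imputed at the training mean (0 after
#' scaling) with a warning. Predictions are Z-scored within the cohort, so
#' higher Z means more resistant than the cohort average.
#'
#' @param models a [ridge_train()] model set.
#' @param bulk_expr [expression_matrix()] or matrix, genes x samples
#'   (typically batch-adjusted).
#' @return Sample x drug matrix of resistance Z-scores (raw predictions in
#'   the `"raw"` attribute).
#' @export
ridge_predict <- function(models, bulk_expr) {
  values <- as_values(bulk_expr)
  present <- intersect(models$features, rownames(values))
  if (!length(present)) stop("no overlapping genes between model and data")
  if (length(present) < 0.5 * length(models$features))
    stop("fewer than 50% of model genes present")
  if (length(present) < length(models$features))
    warning(length(models$features) - length(present),
            " model gene(s) missing; imputed at training mean")
  X <- matrix(0, ncol(values), length(models$features),
              dimnames = list(colnames(values), models$features))
  Xp <- sweep(sweep(t(values[present, , drop = FALSE]), 2,
                    models$center[present], "-"), 2, models$scale[present], "/")
  X[, present] <- Xp
  raw <- vapply(models$models, function(m)
    m$intercept + drop(X %*% m$coefficients), numeric(ncol(values)))
  raw <- matrix(raw, ncol(values),
                dimnames = list(colnames(values), names(models$models)))
  z <- apply(raw, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  z <- matrix(z, nrow = nrow(raw), dimnames = dimnames(raw))
  attr(z, "raw") <- raw
  z
}
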