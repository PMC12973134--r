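#' Inverse distance-weighted k-nearest-neighbour cluster classifier
#'
#' Stores the training metagene-score matrix, its labels and the scaling used
#' to standardise it; queries are standardised with the training parameters.
#'
#' @param train_scores sample x feature training matrix (e.g. ssGSEA metagene
#'   scores).
#' @param labels integer cluster labels of the training samples.
#' @param k neighbour count (1 <= k <= n).
#' @param standardise z-score features on the training data.
#' @return Object of class `knn_classifier`.
#' @export
knn_classifier <- function(train_scores, labels, k = 7, standardise = TRUE) {
  S <- as.matrix(train_scores)
  stopifnot(nrow(S) == length(labels), k >= 1, k <= nrow(S))
  Z <- if (standardise) standardise_cols(S) else S
  structure(list(train = Z, labels = as.integer(labels), k = as.integer(k),
                 center = if (standardise) attr(Z, "center") else rep(0, ncol(S)),
                 scale = if (standardise) attr(Z, "scale") else rep(1, ncol(S)),
                 classes = sort(unique(as.integer(labels)))),
            class = "knn_classifier")
}

#' Assign samples by inverse distance-weighted nearest neighbours
#'
#' Among the `k` nearest training samples of a query, each class scores the
#' sum of inverse Euclidean distances of its neighbours; a zero-distance
#' neighbour short-circuits to its label. Ties break to the lower class
#' label. Normalised class weights are reported as soft assignments.
#'
#' @param clf a [knn_classifier()].
#' @param S_new query sample x feature matrix over the training features.
#' @return A `cluster_assignment` with `labels`, `prob` (soft assignment),
#'   `provenance = "knn"`.
#' @export
knn_assign <- function(clf, S_new) {
  S_new <- as.matrix(S_new)
  if (!identical(colnames(S_new), colnames(clf$train))) {
    miss <- setdiff(colnames(clf$train), colnames(S_new))
    if (length(miss)) stop("feature mismatch; missing: ",
                           paste(head(miss, 5), collapse = ", "))
    S_new <- S_new[, colnames(clf$train), drop = FALSE]
  }
  Z <- sweep(sweep(S_new, 2, clf$center, "-"), 2, clf$scale, "/")
  d2 <- dist_to_centroids(Z, clf$train)
  cls <- clf$classes
  prob <- matrix(0, nrow(Z), length(cls),
                 dimnames = list(rownames(S_new), paste0("cluster_", cls)))
  labels <- integer(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    d <- sqrt(d2[i, ])
    nb <- order(d, seq_along(d))[seq_len(clf$k)]
    if (any(d[nb] == 0)) {
      hit <- clf$labels[nb[d[nb] == 0][1]]
      prob[i, match(hit, cls)] <- 1
      labels[i] <- hit
      next
    }
    w <- tapply(1 / d[nb], factor(clf$labels[nb], levels = cls), sum,
                default = 0)
    prob[i, ] <- w / sum(w)
    labels[i] <- cls[which.max(w)]
  }
  structure(list(labels = stats::setNames(labels, rownames(S_new)),
                 prob = prob, provenance = "knn"),
            class = "cluster_assignment")
}

#' Multinomial elastic-net cluster classifier
#'
#' Fits `glmnet` multinomial models over an alpha grid, choosing the
#' `(alpha, lambda)` pair by cross-validated multinomial deviance with
#' stratified folds (every class present in every fold).
#'
#' @param X sample x feature matrix (e.g. log2 expression of the features
#'   shared with the training modality).
#' @param labels integer cluster labels.
#' @param alpha_grid elastic-net mixing values in [0, 1].
#' @param folds CV fold count.
#' @param seed integer seed.
#' @param standardise let glmnet standardise features internally.
#' @return Object of class `enet_classifier`: the fitted `cv.glmnet` at the
#'   selected alpha, the selected penalties, feature names and classes.
#' @export
fit_enet <- function(X, labels, alpha_grid = c(0.1, 0.5, 0.9), folds = 5,
                     seed = 1L, standardise = TRUE) {
  X <- as.matrix(X)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  set.seed(stage_seed(seed, "enet"))
  # stratified folds: shuffle within class, then deal out fold ids
  foldid <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fits <- lapply(alpha_grid, function(a)
    glmnet::cv.glmnet(X, y, family = "multinomial", alpha = a,
                      foldid = foldid, standardize = standardise,
                      type.measure = "deviance"))
  cvmin <- vapply(fits, function(f) min(f$cvm), numeric(1))
  best <- which.min(cvmin)
  structure(list(fit = fits[[best]], alpha = alpha_grid[best],
                 lambda = fits[[best]]$lambda.min,
                 features = colnames(X), classes = levels(y),
                 seed = seed),
            class = "enet_classifier")
}

#' @export
print.enet_classifier <- function(x, ...) {
  cat(sprintf("<enet_classifier> %d classes, alpha=%.2f lambda=%.4g over %d features\n",
              length(x$classes), x$alpha, x$lambda, length(x$features)))
  invisible(x)
}

#' Assign samples to clusters with a fitted elastic-net classifier
#'
#' Missing model features are imputed as 0 (glmnet works on its own internal
#' standardisation, so this is the feature's training-mean contribution only
#' when the data were centred beforehand) with a warning and a reliability
#' flag; more than half missing is an error. Samples whose maximum class
#' probability falls below `reliability_threshold` are flagged unreliable.
#'
#' @param clf an [fit_enet()] classifier.
#' @param X_new query sample x feature matrix.
#' @param reliability_threshold minimum max-probability for a reliable call.
#' @return `cluster_assignment` with `labels`, `prob`, `reliable` (logical),
#'   `provenance = "enet"`.
#' @export
enet_assign <- function(clf, X_new, reliability_threshold = 0.5) {
  X_new <- as.matrix(X_new)
  miss <- setdiff(clf$features, colnames(X_new))
  if (length(miss) > 0.5 * length(clf$features))
    stop("> 50% of model features missing from query data")
  imputed <- length(miss) > 0
  if (imputed) {
    warning(length(miss), " model feature(s) missing; imputed as 0")
    X_new <- cbind(X_new, matrix(0, nrow(X_new), length(miss),
                                 dimnames = list(rownames(X_new), miss)))
  }
  X_new <- X_new[, clf$features, drop = FALSE]
  prob <- drop(predict(clf$fit, newx = X_new, s = "lambda.min",
                       type = "response"))
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1,
                                         dimnames = list(rownames(X_new), clf$classes))
  labels <- as.integer(clf$classes[max.col(prob, ties.method = "first")])
  reliable <- apply(prob, 1, max) >= reliability_threshold
  structure(list(labels = stats::setNames(labels, rownames(X_new)),
                 prob = prob,
                 reliable = stats::setNames(reliable, rownames(X_new)),
                 imputed_features = miss, provenance = "enet"),
            class = "cluster_assignment")
}
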