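#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, features are ranked by expression (descending, average
#' ranks for ties). Walking down the ranked list, the enrichment score of a
#' set is the sum of the difference between the weighted in-set empirical
#' CDF -- where a feature at absolute rank-from-top `r` carries weight
#' `r^alpha` -- and the unweighted out-of-set ECDF. With `normalise = TRUE`
#' all scores are divided by the range (max - min) of the whole score matrix,
#' the usual ssGSEA normalisation.
#'
#' Scores depend on expression only through within-sample ranks, so any
#' strictly monotone per-sample transform leaves them unchanged.
#'
#' @param X [expression_matrix()] or matrix, features x samples.
#' @param sets named list of character vectors (e.g. [extract_metagenes()]
#'   `$sets`, or [read_gmt()] output).
#' @param alpha rank-weighting exponent.
#' @param normalise divide by the overall score range.
#' @return Sample x set score matrix with attributes `method`, `alpha`.
#' @export
ssgsea_scores <- function(X, sets, alpha = 0.25, normalise = TRUE) {
  values <- as_values(X)
  if (inherits(sets, "metagene_set")) sets <- sets$sets
  n <- nrow(values)
  keep <- vapply(sets, function(s) {
    ov <- sum(rownames(values) %in% s)
    ov > 0 && ov < n
  }, logical(1))
  full <- vapply(sets, function(s) sum(rownames(values) %in% s) == n, logical(1))
  if (any(full)) stop("gene set covering all features: ",
                      paste(names(sets)[full], collapse = ", "))
  if (any(!keep)) {
    warning(sum(!keep), " gene set(s) without feature overlap dropped")
    sets <- sets[keep]
  }
  if (!length(sets)) stop("no scorable gene sets")
  member <- vapply(sets, function(s) rownames(values) %in% s,
                   logical(n))                       # feature x set
  scores <- matrix(0, ncol(values), length(sets),
                   dimnames = list(colnames(values), names(sets)))
  in_sizes <- colSums(member)
  for (j in seq_len(ncol(values))) {
    r <- rank(-values[, j], ties.method = "average") # 1 = top feature
    ord <- order(r, seq_len(n))                      # descending expression
    w <- (n - r + 1)^alpha                           # absolute rank from top
    m_ord <- member[ord, , drop = FALSE]
    w_ord <- w[ord]
    win <- m_ord * w_ord
    cdf_in <- apply(win, 2, cumsum)
    cdf_in <- sweep(cdf_in, 2, colSums(win), "/")
    cdf_out <- apply(!m_ord, 2, cumsum)
    cdf_out <- sweep(cdf_out, 2, n - in_sizes, "/")
    scores[j, ] <- colSums(cdf_in - cdf_out)
  }
  if (normalise) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "method") <- "ssgsea"
  attr(scores, "alpha") <- alpha
  scores
}

#' Univariable linear-model activity scores for weighted regulons
#'
#' The activity of a regulon in a sample is the t-statistic of the slope from
#' the simple linear regression of the standardised sample profile on the
#' regulon's weight vector (non-targets carry weight 0). Positive scores mean
#' the profile moves with the regulon's signed targets.
#'
#' @param sample_profile named numeric vector of per-feature statistics
#'   (e.g. one sample's expression, or log2 fold changes).
#' @param regulons named list; each element either a character vector of
#'   targets (weights +1) or a named numeric vector of signed weights.
#' @param min_targets minimum overlapping weighted targets per regulon.
#' @return Named numeric vector of t-statistics, one per regulon.
#' @export
lm_activity_uni <- function(sample_profile, regulons, min_targets = 3) {
  y <- scale(sample_profile)[, 1]
  names(y) <- names(sample_profile)
  vapply(regulons, function(reg) {
    w <- regulon_weights(reg, names(y))
    if (sum(w != 0) < min_targets)
      stop("regulon with fewer than ", min_targets, " overlapping targets")
    if (stats::sd(w) == 0) stop("zero-variance weight vector")
    fit <- stats::lm(y ~ w)
    summary(fit)$coefficients["w", "t value"]
  }, numeric(1))
}

regulon_weights <- function(reg, features) {
  w <- stats::setNames(numeric(length(features)), features)
  if (is.character(reg)) {
    w[intersect(reg, features)] <- 1
  } else {
    hit <- intersect(names(reg), features)
    w[hit] <- reg[hit]
  }
  w
}

#' Multivariable linear-model activity scores for pathway weight matrices
#'
#' Regresses the standardised profile on all pathway weight columns jointly;
#' activities are the coefficient t-values, so shared footprint genes are
#' apportioned between pathways instead of double-counted.
#'
#' @param sample_profile named numeric vector.
#' @param pathway_weights feature x pathway numeric weight matrix (rows named
#'   by feature; missing features count as weight 0).
#' @return Named numeric vector of per-pathway t-values.
#' @export
lm_activity_multi <- function(sample_profile, pathway_weights) {
  y <- scale(sample_profile)[, 1]
  W <- matrix(0, length(y), ncol(pathway_weights),
              dimnames = list(names(sample_profile), colnames(pathway_weights)))
  hit <- intersect(rownames(pathway_weights), names(sample_profile))
  W[hit, ] <- pathway_weights[hit, , drop = FALSE]
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[-seq_len(qrW$rank)]]
    stop("rank-deficient pathway design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ W)
  tv <- summary(fit)$coefficients[-1, "t value"]
  stats::setNames(tv, colnames(W))
}
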