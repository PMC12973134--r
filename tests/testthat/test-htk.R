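# 3 spherical Gaussian clusters in a few informative features plus noise.
htk_fixture <- function(n_per = 30, p_info = 10, p_noise = 90, sep = 6,
                        seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, p_info)
  centers[1, ] <- sep / 2
  centers[2, ] <- -sep / 2
  centers[3, seq_len(p_info / 2)] <- sep / 2
  centers[3, -seq_len(p_info / 2)] <- -sep / 2
  S <- do.call(rbind, lapply(1:3, function(c)
    matrix(rnorm(n_per * p_info, 0, 1), n_per) +
      matrix(centers[c, ], n_per, p_info, byrow = TRUE)))
  S <- cbind(S, matrix(rnorm(3 * n_per * p_noise), 3 * n_per))
  colnames(S) <- c(sprintf("info_%02d", seq_len(p_info)),
                   sprintf("noise_%02d", seq_len(p_noise)))
  rownames(S) <- sprintf("s%03d", seq_len(nrow(S)))
  list(S = S, truth = rep(1:3, each = n_per))
}

test_that("lambda 0 reproduces reference k-means objectives from shared inits", {
  for (seed in 1:20) {
    set.seed(seed)
    S <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(sprintf("s%02d", 1:60), sprintf("f%d", 1:4)))
    fit <- fit_htkmeans(S, k = 3, lambda = 0, n_init = 1, seed = seed,
                        standardise = FALSE)
    # rebuild the same k-means++ start from the same seeded stream
    set.seed(stage_seed(seed, "htkmeans"))
    init <- uroclust:::kmeanspp_init(S, 3)
    ref <- suppressWarnings(kmeans(S, centers = init, algorithm = "Lloyd",
                                   iter.max = 200))
    expect_equal(fit$objective, ref$tot.withinss, tolerance = 1e-8)
  }
})

test_that("moderate shrinkage silences pure-noise features and recovers truth", {
  fx <- htk_fixture()
  fit <- fit_htkmeans(fx$S, k = 3, lambda = 0.3, n_init = 20, seed = 2)
  act <- fit$active_features
  expect_true(all(!act[grepl("^noise", names(act))]))
  expect_true(all(act[grepl("^info", names(act))]))
  expect_equal(adjusted_rand(fit$assignments, fx$truth), 1)
  # inactive centroid entries sit at the global feature mean
  inact <- which(!act)
  for (j in head(inact, 5))
    expect_equal(unname(fit$centroids[, j]),
                 rep(unname(fit$global_means[j]), 3), tolerance = 1e-12)
})

test_that("penalised objective is non-increasing within a restart", {
  fx <- htk_fixture(seed = 3)
  fit <- fit_htkmeans(fx$S, k = 3, lambda = 0.2, n_init = 1, seed = 5)
  expect_lte(max(diff(fit$objective_trace)), 1e-8)
})

test_that("active sets are nested along lambda for fixed assignments", {
  fx <- htk_fixture(seed = 4)
  fit <- fit_htkmeans(fx$S, k = 3, lambda = 0, n_init = 10, seed = 6)
  # between-cluster SS per feature under the converged assignment
  Z <- scale(fx$S)
  asg <- fit$assignments
  gm <- colMeans(Z)
  bcss <- colSums(as.numeric(table(asg)) * (apply(Z, 2, function(x)
    tapply(x, asg, mean)) - matrix(gm, 3, ncol(Z), byrow = TRUE))^2)
  lambdas <- seq(0, max(bcss) / nrow(Z) * 1.2, length.out = 12)
  active_counts <- vapply(lambdas, function(l) sum(bcss > l * nrow(Z)),
                          numeric(1))
  expect_true(all(diff(active_counts) <= 0))
  expect_identical(active_counts[length(active_counts)], 0)
})

test_that("over-shrunk models fail loudly", {
  fx <- htk_fixture(n_per = 10, p_info = 4, p_noise = 4, seed = 7)
  expect_error(fit_htkmeans(fx$S, k = 3, lambda = 1e6, n_init = 3, seed = 1),
               "fully shrunk")
})

test_that("prediction is self-consistent and resolves ties to the lower index", {
  fx <- htk_fixture(seed = 8)
  fit <- fit_htkmeans(fx$S, k = 3, lambda = 0.2, n_init = 10, seed = 3)
  pred <- predict_htk(fit, fx$S)
  expect_identical(unname(pred$labels), unname(fit$assignments))

  # a point placed exactly at a centroid lands there with distance 0
  act <- which(fit$active_features)
  z_cent <- fit$centroids[2, ]
  raw <- z_cent * fit$scaling$scale + fit$scaling$center
  q <- matrix(raw, 1, dimnames = list("q", names(raw)))
  pq <- predict_htk(fit, q)
  expect_identical(unname(pq$labels), 2L)
  expect_lt(pq$distance[1, 2], 1e-12)

  expect_error(predict_htk(fit, fx$S[, 1:3]), "missing model features")
})

test_that("tuning prefers the true cluster count on an easy fixture", {
  fx <- htk_fixture(n_per = 20, p_info = 8, p_noise = 12, seed = 9)
  tab <- tune_htkmeans(fx$S, k_grid = 2:4, lambda_grid = c(0, 0.2),
                       folds = 3, n_init = 5, seed = 11)
  expect_identical(tab$k[1], 3L)
  expect_true(all(tab$cv_stability >= 0 & tab$cv_stability <= 1))
})

test_that("clustering quality metrics separate clean from shuffled labels", {
  fx <- htk_fixture(seed = 10)
  fit <- fit_htkmeans(fx$S, k = 3, lambda = 0.2, n_init = 10, seed = 4)
  q <- clustering_quality(fit, fx$S)
  expect_gt(q$silhouette, 0.3)
  expect_gt(q$explained_variance, 0.2)
  expect_identical(dim(q$intercluster_distance), c(3L, 3L))

  # random labels on structureless data have silhouette near zero
  set.seed(13)
  sils <- vapply(1:10, function(i) {
    Srand <- matrix(rnorm(60 * 6), 60, 6)
    uroclust:::mean_silhouette(sample(1:3, 60, replace = TRUE), Srand)
  }, numeric(1))
  expect_lt(abs(mean(sils)), 0.05)

  # duplicated samples split across clusters score negative silhouette
  Sdup <- rbind(fx$S[1:10, ], fx$S[1:10, ])
  lab <- rep(1:2, each = 10)
  sil <- cluster::silhouette(lab, dist(Sdup))
  expect_true(all(sil[, "sil_width"] < 0))
})
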