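test_that("eta squared matches an independent sums-of-squares decomposition", {
  set.seed(1)
  for (rep in 1:5) {
    X <- toy_matrix(8, 30, seed = rep)
    labels <- setNames(sample(1:3, 30, replace = TRUE, prob = c(.4, .3, .3)),
                       colnames(X))
    while (min(table(labels)) < 3)
      labels <- setNames(sample(1:3, 30, replace = TRUE), colnames(X))
    res <- diff_features(X, labels)
    for (g in rownames(X)) {
      x <- X[g, ]
      ssw <- sum(unlist(lapply(split(x, labels), function(v)
        sum((v - mean(v))^2))))
      sst <- sum((x - mean(x))^2)
      eta2_oracle <- 1 - ssw / sst
      expect_equal(res$anova$eta2[res$anova$feature == g], eta2_oracle,
                   tolerance = 1e-10)
    }
  }
})

test_that("a printed-design fixture reproduces the brute-force eta squared", {
  # two groups of 5, means 0 and 1, within-SD exactly 1
  g1 <- c(-1, -0.5, 0, 0.5, 1); g1 <- (g1 - mean(g1)) / sd(g1)
  g2 <- g1 + 1
  X <- matrix(c(g1, g2), 1, 10,
              dimnames = list("f", sprintf("s%02d", 1:10)))
  labels <- setNames(rep(1:2, each = 5), colnames(X))
  res <- diff_features(X, labels)
  ssb <- 5 * (0 - 0.5)^2 + 5 * (1 - 0.5)^2
  sst <- ssb + 2 * 4 * 1      # SS_within = (n-1) * SD^2 per group
  expect_equal(res$anova$eta2, ssb / sst, tolerance = 1e-10)
})

test_that("null and planted fixtures flag the right clusters", {
  set.seed(2)
  # identical cluster means: eta2 near 0, nothing flagged
  Xnull <- toy_matrix(20, 60, seed = 3)
  labels <- setNames(rep(1:3, each = 20), colnames(Xnull))
  res0 <- diff_features(Xnull, labels)
  expect_false(any(res0$clusters$flag))

  # cluster 3 shifted far up on one feature
  X <- toy_matrix(5, 9, seed = 4)
  X[1, ] <- rep(c(1, 1, 4), each = 3) + rnorm(9, 0, 1e-3)
  labels <- setNames(rep(1:3, each = 3), colnames(X))
  res <- diff_features(X, labels)
  expect_gt(res$anova$eta2[res$anova$feature == "g01"], 0.99)
  row3 <- res$clusters[res$clusters$feature == "g01" & res$clusters$cluster == 3, ]
  expect_true(row3$flag)
  expect_gt(row3$log2_diff, 0)
})

test_that("zero-variance features are skipped with a message", {
  X <- toy_matrix(4, 12, seed = 5)
  X[2, ] <- 7
  labels <- setNames(rep(1:3, each = 4), colnames(X))
  expect_message(res <- diff_features(X, labels), "zero-variance")
  expect_false("g02" %in% res$anova$feature)
})

test_that("cohort sharing respects thresholds and direction consistency", {
  fake <- function(features, cluster, sign) {
    structure(list(clusters = data.frame(
      feature = features, cluster = cluster,
      log2_diff = sign, flag = TRUE)), class = "diff_result")
  }
  res <- list(a = fake("g1", 1, 1), b = fake("g1", 1, 1), c = fake("g1", 1, -1))
  # min_cohorts = 1: union
  expect_identical(shared_features(res, 1, direction_consistent = FALSE),
                   list(cluster_1 = "g1"))
  # flagged in 3 cohorts but discordant sign
  expect_identical(shared_features(res, 3, direction_consistent = TRUE),
                   list(cluster_1 = character(0)))
  # 2 of 3 with min 3: excluded
  res2 <- list(a = fake("g1", 1, 1), b = fake("g1", 1, 1),
               c = fake("g2", 1, 1))
  expect_identical(shared_features(res2, 3)$cluster_1, character(0))
  expect_error(shared_features(res, 5), "exceeds")
})

test_that("planted multi-cohort modules are recovered with little leakage", {
  cfgs <- lapply(1:6, function(i)
    sim_config(n_cohorts = 1, samples_per_cohort = 60, n_genes = 200,
               n_modules = 20, seed = 300 + i))
  results <- lapply(cfgs, function(cfg) {
    st <- simulate_multicohort(cfg)
    diff_features(st$cohorts[[1]]$values, st$truth$labels)
  })
  shared <- shared_features(results, min_cohorts = 5)
  st <- simulate_multicohort(cfgs[[1]])
  informative <- names(st$truth$module_of)[
    !is.na(st$truth$module_of) & st$truth$module_of <= 6]
  planted_up_c1 <- names(st$truth$module_of)[
    !is.na(st$truth$module_of) & st$truth$module_of == 1]
  expect_gte(length(intersect(shared$cluster_1, planted_up_c1)),
             0.8 * length(planted_up_c1))
  background <- names(st$truth$module_of)[is.na(st$truth$module_of) |
                                            st$truth$module_of > 6]
  leakage <- length(intersect(unlist(shared), background)) /
    max(1, length(background))
  expect_lte(leakage, 0.05)
})

test_that("DerSimonian-Laird pooling matches its textbook formula and metafor", {
  # identical estimates: tau2 = 0, pooled = the common value
  m <- dl_meta(rep(1.3, 4), rep(0.2, 4))
  expect_equal(m$tau2, 0)
  expect_equal(m$estimate, 1.3)

  # two equal-SE studies with Q <= 1 pool to the plain mean
  m2 <- dl_meta(c(0.8, 1.0), c(0.5, 0.5))
  expect_lte(m2$Q, 1)
  expect_equal(m2$estimate, 0.9, tolerance = 1e-12)

  # heterogeneous 5-study fixture vs independent implementations
  y <- c(0.2, 0.8, -0.1, 1.4, 0.6)
  se <- c(0.15, 0.3, 0.2, 0.25, 0.1)
  m5 <- dl_meta(y, se)
  w <- 1 / se^2
  Q <- sum(w * (y - sum(w * y) / sum(w))^2)
  tau2 <- max(0, (Q - 4) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  expect_equal(m5$estimate, sum(ws * y) / sum(ws), tolerance = 1e-10)
  expect_equal(m5$tau2, tau2, tolerance = 1e-10)
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(m5$estimate, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m5$tau2, rma$tau2, tolerance = 1e-10)

  expect_warning(single <- dl_meta(1.1, 0.3), "single study")
  expect_equal(single$tau2, 0)
  expect_error(dl_meta(c(1, 2), c(0.1, -0.2)), "positive")
})

test_that("marker AUC equals exhaustive pair counting and the pROC oracle", {
  # 4-sample toy: the top two samples form the cluster -> AUC 1
  X <- matrix(c(1, 2, 3, 4), 1, 4,
              dimnames = list("f", paste0("s", 1:4)))
  labels <- setNames(c(2, 2, 1, 1), colnames(X))
  tab <- marker_auc(X, labels)
  expect_equal(tab$auc[tab$cluster == 1], 1)
  expect_equal(tab$auc[tab$cluster == 2], 0)
  expect_true(tab$marker[tab$cluster == 1])

  # label-independent feature at large n scores about one half
  set.seed(6)
  Xn <- matrix(rnorm(4000), 1, 4000,
               dimnames = list("f", sprintf("s%04d", 1:4000)))
  ln <- setNames(sample(1:2, 4000, replace = TRUE), colnames(Xn))
  aucs <- marker_auc(Xn, ln)$auc
  expect_lt(max(abs(aucs - 0.5)), 0.05)

  # constant feature: 0.5 by convention
  Xc <- matrix(3, 1, 10, dimnames = list("f", paste0("s", 1:10)))
  lc <- setNames(rep(1:2, 5), colnames(Xc))
  expect_equal(marker_auc(Xc, lc)$auc, c(0.5, 0.5))

  # antisymmetry on tie-free data, and agreement with pROC
  set.seed(7)
  x <- rnorm(40)
  Xa <- rbind(f = x); colnames(Xa) <- sprintf("s%02d", 1:40)
  la <- setNames(rep(1:2, each = 20), colnames(Xa))
  a_pos <- marker_auc(Xa, la)$auc[1]
  a_neg <- marker_auc(-Xa, la)$auc[1]
  expect_equal(a_pos + a_neg, 1, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  oracle <- as.numeric(pROC::auc(pROC::roc(la == 1, x, quiet = TRUE,
                                           direction = "<")))
  expect_equal(a_pos, oracle, tolerance = 1e-10)
})

test_that("FDR columns of the caller dominate p and preserve its ordering", {
  X <- toy_matrix(40, 30, seed = 9)
  labels <- setNames(rep(1:3, each = 10), colnames(X))
  res <- diff_features(X, labels)
  expect_true(all(res$anova$q >= res$anova$p - 1e-15))
  expect_true(all(res$clusters$q >= res$clusters$p - 1e-15))
  o <- order(res$anova$p)
  expect_true(all(diff(res$anova$q[o]) >= -1e-15))
})
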