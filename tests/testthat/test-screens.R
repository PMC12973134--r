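test_that("bootstrap handles zero-variance, symmetric and planted effects", {
  set.seed(1)
  labels <- setNames(rep(1:2, each = 5), paste0("l", 1:10))
  chronos <- matrix(rnorm(10 * 3, 0, 0.1), 10,
                    dimnames = list(names(labels), c("gA", "gB", "gC")))
  chronos[labels == 1, "gA"] <- 0.7          # constant score in cluster 1
  boot <- chronos_bootstrap(chronos, labels, n_boot = 400, seed = 2)
  rowA <- boot$effects[boot$effects$gene == "gA" & boot$effects$cluster == 1, ]
  expect_equal(rowA$lower, 0.7)
  expect_equal(rowA$upper, 0.7)
  expect_true(rowA$effect)

  # scores centred on zero: no effect flag, CI brackets the sample mean
  rowB <- boot$effects[boot$effects$gene == "gB" & boot$effects$cluster == 2, ]
  expect_false(rowB$effect)
  expect_true(rowB$lower <= rowB$mean && rowB$mean <= rowB$upper)

  # bootstrap adds uncertainty, not bias
  bm <- mean(chronos[labels == 2, "gB"])
  expect_lt(abs(rowB$mean - bm), 1e-12)

  # difference p small for the planted contrast
  dA <- boot$differences[boot$differences$gene == "gA", ]
  expect_lt(dA$p, 0.05)

  lab_bad <- setNames(c(rep(1, 9), 2), names(labels))
  expect_warning(chronos_bootstrap(chronos, lab_bad, n_boot = 100, seed = 1),
                 "single cell line")
})

test_that("CI coverage of a zero-mean gene is near nominal", {
  labels <- setNames(rep(1, 12), paste0("l", 1:12))
  cover <- vapply(1:60, function(r) {
    set.seed(r)
    ch <- matrix(rnorm(12, 0, 1), 12, 1,
                 dimnames = list(names(labels), "g"))
    b <- chronos_bootstrap(ch, labels, n_boot = 300, seed = r)
    b$effects$lower <= 0 && 0 <= b$effects$upper
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("ridge collapses to OLS at lambda 0 and to the mean at huge lambda", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30, 4,
              dimnames = list(paste0("l", 1:30), paste0("g", 1:4)))
  beta <- c(1.5, -2, 0.5, 0)
  y <- drop(X %*% beta) + rnorm(30, 0, 0.1)
  fit0 <- ridge_train(X, cbind(d = y), lambda_grid = 0, folds = 3, seed = 1)
  Z <- scale(X)
  ols <- coef(lm(y ~ Z))
  expect_equal(unname(fit0$models$d$coefficients), unname(ols[-1]),
               tolerance = 1e-8)
  expect_equal(fit0$models$d$intercept, unname(ols[1]), tolerance = 1e-8)

  fit_inf <- ridge_train(X, cbind(d = y), lambda_grid = 1e9, folds = 3, seed = 1)
  expect_lt(max(abs(fit_inf$models$d$coefficients)), 1e-5)
  pred <- ridge_predict(fit_inf, t(X))
  expect_lt(max(abs(attr(pred, "raw") - mean(y))), 1e-4)
})

test_that("a tiny fixture matches the closed-form ridge solution", {
  X <- matrix(c(1, 2, 3, 0, 1, 1), 3, 2,
              dimnames = list(paste0("l", 1:3), c("g1", "g2")))
  y <- c(1, 2, 2)
  fit <- ridge_train(X, cbind(d = y), lambda_grid = 1, folds = 3, seed = 2)
  Z <- scale(X)
  oracle <- solve(crossprod(Z) + diag(1, 2), crossprod(Z, y - mean(y)))
  expect_equal(unname(fit$models$d$coefficients), unname(drop(oracle)),
               tolerance = 1e-10)
})

test_that("training error is monotone in lambda and constant responses skipped", {
  set.seed(4)
  X <- matrix(rnorm(25 * 3), 25, 3,
              dimnames = list(paste0("l", 1:25), paste0("g", 1:3)))
  y <- drop(X %*% c(1, -1, 2)) + rnorm(25, 0, 0.2)
  Z <- scale(X)
  lambdas <- c(0, 0.5, 2, 10, 100)
  mses <- vapply(lambdas, function(l) {
    b <- solve(crossprod(Z) + diag(l, 3), crossprod(Z, y - mean(y)))
    mean((y - mean(y) - drop(Z %*% b))^2)
  }, numeric(1))
  expect_true(all(diff(mses) >= -1e-12))

  expect_warning(
    fit <- ridge_train(X, cbind(const = rep(1, 25), ok = y),
                       lambda_grid = c(0.1, 1), folds = 3, seed = 3),
    "constant response")
  expect_identical(names(fit$models), "ok")
})

test_that("bulk prediction reuses training geometry and Z-scores per cohort", {
  set.seed(5)
  X <- matrix(rnorm(20 * 5, 8), 20, 5,
              dimnames = list(paste0("l", 1:20), paste0("g", 1:5)))
  y <- drop(scale(X) %*% c(2, 0, -1, 0, 1)) + rnorm(20, 0, 0.05)
  fit <- ridge_train(X, cbind(d = y), lambda_grid = c(0.01, 0.1), folds = 4,
                     seed = 4)
  # a bulk sample equal to a training line reproduces its fitted value
  bulk <- t(X)
  pred <- ridge_predict(fit, bulk)
  m <- fit$models$d
  fitted1 <- m$intercept +
    drop(((X[1, ] - fit$center) / fit$scale) %*% m$coefficients)
  expect_equal(attr(pred, "raw")[1, "d"], fitted1, tolerance = 1e-10)

  # identical samples give all-zero Z-scores
  same <- matrix(X[1, ], 5, 6, dimnames = list(colnames(X), paste0("s", 1:6)))
  pred_same <- ridge_predict(fit, same)
  expect_equal(unname(pred_same[, "d"]), rep(0, 6))

  expect_error(ridge_predict(fit, bulk[1:2, , drop = FALSE]), "50%")
})

test_that("a planted sensitivity program shifts one cluster's resistance Z", {
  set.seed(6)
  n_lines <- 40
  X <- matrix(rnorm(n_lines * 10, 8), n_lines, 10,
              dimnames = list(paste0("l", 1:n_lines), paste0("g", 1:10)))
  y <- 2 * scale(X[, "g1"])[, 1] + rnorm(n_lines, 0, 0.2)  # g1 drives resistance
  fit <- ridge_train(X, cbind(d = y), lambda_grid = c(0.1, 1), folds = 4,
                     seed = 5)
  # bulk cohort where cluster 2 under-expresses g1 -> lower resistance Z
  bulk <- matrix(rnorm(10 * 60, 8), 10, 60,
                 dimnames = list(colnames(X), paste0("s", 1:60)))
  cl <- rep(c(1, 2), each = 30)
  bulk["g1", cl == 2] <- bulk["g1", cl == 2] - 3
  z <- ridge_predict(fit, bulk)
  expect_lt(mean(z[cl == 2, "d"]), mean(z[cl == 1, "d"]) - 0.5)
})
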