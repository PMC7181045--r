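test_that("component density matches the standard normal closed form", {
  p <- gmm_params(1, matrix(0), array(1, c(1, 1, 1)))
  expect_equal(gmm_component_density(0, 1, p), 1 / sqrt(2 * pi))
  # quadrature: the 1-D density integrates to ~1
  grid <- seq(-8, 8, by = 0.01)
  dens <- gmm_component_density(matrix(grid, ncol = 1), 1, p)
  expect_equal(sum(dens) * 0.01, 1, tolerance = 1e-6)
  # density is maximal at the mean along any ray
  ray <- seq(0, 3, by = 0.1)
  expect_true(all(diff(gmm_component_density(matrix(ray, ncol = 1), 1, p)) < 0))
})

test_that("single-component fit is the closed-form MLE", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3)
  fit <- gmm_fit(X, 1)
  expect_equal(fit$params$weights, 1)
  expect_equal(drop(fit$params$means), colMeans(X))
  expect_equal(fit$params$covariances[, , 1], cov(X) * 19 / 20,
               tolerance = 1e-12)
})

test_that("EM recovers separated spherical clusters and ascends monotonically", {
  set.seed(22)
  mu <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(200), 100, 2), 2, mu[k, ], "+")))
  fit <- gmm_fit(X, 3, seed = 1)
  truth <- rep(1:3, each = 100)
  centroids <- t(vapply(1:3, function(k)
    colMeans(X[truth == k, ]), numeric(2)))
  # match each fitted mean to its nearest generating cluster centroid:
  # at 10-sigma separation EM should recover the centroids themselves
  nearest <- apply(fit$params$means, 1, function(mk)
    which.min(colSums((t(centroids) - mk)^2)))
  expect_setequal(nearest, 1:3)
  err <- sqrt(rowSums((fit$params$means - centroids[nearest, ])^2))
  expect_lt(max(err), 0.1)               # within 0.1 sigma
  expect_true(all(diff(fit$trace$loglik) > -1e-9))
  # hard assignment matches the generator labels up to permutation
  truth <- rep(1:3, each = 100)
  expect_gt(adjusted_rand_index(gmm_hard_assign(fit$params, X), truth), 0.99)
})

test_that("responsibilities are simplex rows computed stably", {
  p1 <- gmm_params(1, matrix(c(0, 0), 1), array(diag(2), c(2, 2, 1)))
  R1 <- gmm_responsibilities(p1, matrix(rnorm(10), 5, 2))
  expect_true(all(R1 == 1))
  p2 <- gmm_params(c(0.5, 0.5), rbind(c(0, 0), c(50, 0)),
                   array(diag(2), c(2, 2, 2)))
  R2 <- gmm_responsibilities(p2, matrix(c(0, 0), 1))
  expect_gt(R2[1, 1], 0.999)
  set.seed(23)
  X <- matrix(rnorm(40, sd = 30), 20, 2)  # far tails: needs log-space
  R <- gmm_responsibilities(p2, X)
  expect_equal(rowSums(R), rep(1, 20), tolerance = 1e-12)
  expect_true(all(R >= 0))
})

test_that("BIC decomposes into -2 logL plus the chosen penalty", {
  set.seed(24)
  X <- matrix(rnorm(100), 50, 2)
  fit <- gmm_fit(X, 2, seed = 1)
  ll <- gmm_loglik(fit$params, X)
  expect_equal(gmm_bic(fit$params, X), -2 * ll + 3 * 2 * log(50))
  npar <- (2 - 1) + 2 * 2 + 2 * 2 * 3 / 2
  expect_equal(gmm_bic(fit$params, X, penalty = "free-params"),
               -2 * ll + npar * log(50))
})

test_that("component selection finds null and clustered structure", {
  set.seed(25)
  X1 <- matrix(rnorm(160), 80, 2)
  expect_equal(gmm_select_k(X1, k_range = 1:3, seeds = 1:3)$k, 1)
  mu <- rbind(c(0, 0), c(12, 0), c(0, 12))
  X3 <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(120), 60, 2), 2, mu[k, ], "+")))
  sel <- gmm_select_k(X3, k_range = 1:5, seeds = 1:3)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$table), 5)
})

test_that("fits are reproducible from their seed", {
  set.seed(26)
  X <- matrix(rnorm(120), 60, 2)
  f1 <- gmm_fit(X, 2, seed = 5)
  f2 <- gmm_fit(X, 2, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$trace$loglik, f2$trace$loglik)
})

test_that("log-likelihood agrees with an independent mixture implementation", {
  set.seed(27)
  mu <- rbind(c(0, 0), c(8, 0))
  X <- rbind(sweep(matrix(rnorm(160), 80, 2), 2, mu[1, ], "+"),
             sweep(matrix(rnorm(160), 80, 2), 2, mu[2, ], "+"))
  ours <- gmm_fit(X, 2, seed = 1)
  suppressMessages(library(mclust))  # Mclust needs its package attached
  theirs <- Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(ours$loglik, theirs$loglik, tolerance = 1e-3)
})

test_that("degenerate mixtures are refused rather than fitted", {
  set.seed(28)
  X <- matrix(rnorm(24), 12, 8)   # 12 points cannot support 2 full 8-D comps
  expect_error(gmm_fit(X, 3), "degenerate|at least K")
})
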