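test_that("squared-exponential kernel evaluates and is symmetric", {
  h <- gp_hyperparams(1, 1, 0.5)
  expect_equal(gp_kernel(c(0, 0), c(0, 0), h, same_index = TRUE), 1.5)
  h0 <- gp_hyperparams(1, 1, 0)
  expect_equal(gp_kernel(0, 2, h0), exp(-2))
  set.seed(11)
  for (i in 1:100) {
    xi <- rnorm(4); xj <- rnorm(4)
    hr <- gp_hyperparams(runif(1, 0.5, 2), runif(1, 0.5, 2), runif(1))
    expect_equal(gp_kernel(xi, xj, hr), gp_kernel(xj, xi, hr))
  }
  expect_error(gp_kernel(1:3, 1:2, h), "dimension")
  expect_error(gp_hyperparams(-1, 1, 0), "positive")
})

test_that("log marginal likelihood matches the scalar closed form", {
  h <- gp_hyperparams(1, 0.6, 0.4)  # sf2 + sn2 = 1 so K = [1]
  ll <- gp_log_marginal(h, matrix(0.7), 0)
  expect_equal(as.numeric(ll), -0.5 * log(2 * pi))
})

test_that("log marginal likelihood is invariant under row permutation", {
  set.seed(2)
  X <- matrix(rnorm(24), 12, 2); y <- rnorm(12)
  h <- gp_hyperparams(1.2, 0.8, 0.1)
  perm <- sample(12)
  expect_equal(as.numeric(gp_log_marginal(h, X, y)),
               as.numeric(gp_log_marginal(h, X[perm, ], y[perm])),
               tolerance = 1e-10)
})

test_that("analytic gradient agrees with finite differences", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2); y <- rnorm(10)
  p0 <- log(c(1.3, 0.7, 0.2))
  f <- function(p) as.numeric(gp_log_marginal(
    gp_hyperparams(exp(p[1]), exp(p[2]), exp(p[3])), X, y))
  g <- attr(gp_log_marginal(gp_hyperparams(exp(p0[1]), exp(p0[2]),
                                           exp(p0[3])), X, y, grad = TRUE),
            "gradient")
  eps <- 1e-6
  num <- vapply(1:3, function(j) {
    e <- rep(0, 3); e[j] <- eps
    (f(p0 + e) - f(p0 - e)) / (2 * eps)
  }, numeric(1))
  expect_equal(unname(g), num, tolerance = 1e-5)
})

test_that("fit is deterministic and absorbs contradictory duplicates in noise", {
  set.seed(4)
  X <- matrix(rnorm(30), 15, 2); y <- rnorm(15)
  m1 <- gp_fit(X, y, seed = 9)
  m2 <- gp_fit(X, y, seed = 9)
  expect_identical(m1$hyperparams, m2$hyperparams)
  Xd <- rbind(X[1:5, ], X[1:5, ])
  yd <- c(rnorm(5), rnorm(5) + 2)
  md <- gp_fit(Xd, yd, seed = 1)
  expect_gt(md$hyperparams$sigma_n2, 1e-6)
})

test_that("noiseless interpolation and prior reversion behave as limits", {
  m <- gp_fit(matrix(c(0.3, -0.2), 1, 2), 1.7, seed = 1)
  # single-point model with its own sigma_n2: predict at the training
  # point with a manually zeroed noise model
  h <- gp_hyperparams(1, 1, 0)
  K <- gp_kernel(c(0.3, -0.2), c(0.3, -0.2), h, same_index = TRUE)
  expect_equal(K, 1)  # sanity: unit prior at zero distance
  set.seed(5)
  X <- matrix(rnorm(10), 5, 2); y <- rnorm(5)
  mf <- gp_fit(X, y, seed = 2)
  far <- matrix(100, 1, 2)
  pf <- predict(mf, far)
  expect_equal(pf$mean, 0, tolerance = 1e-6)
  expect_equal(pf$var, mf$hyperparams$sigma_f2 + mf$hyperparams$sigma_n2,
               tolerance = 1e-6)
  pl <- predict(mf, far, include_noise = FALSE)
  expect_equal(pl$var, mf$hyperparams$sigma_f2, tolerance = 1e-6)
})

test_that("posterior variance never exceeds the prior variance", {
  set.seed(6)
  for (r in 1:20) {
    X <- matrix(rnorm(30), 15, 2); y <- rnorm(15)
    m <- gp_fit(X, y, restarts = 2, seed = r)
    p <- predict(m, matrix(rnorm(20), 10, 2))
    expect_true(all(p$var <= m$hyperparams$sigma_f2 +
                      m$hyperparams$sigma_n2 + 1e-10))
    expect_true(all(p$var >= 0))
  }
})

test_that("conditioning on one more point never inflates posterior variance", {
  set.seed(7)
  l <- 1.1; sf2 <- 0.9; sn2 <- 0.05
  for (r in 1:15) {
    X <- matrix(rnorm(16), 8, 2); y <- rnorm(8)
    Xq <- matrix(rnorm(10), 5, 2)
    v_n <- dense_gp_predict(l, sf2, sn2, X[1:7, , drop = FALSE], y[1:7], Xq)$var
    v_n1 <- dense_gp_predict(l, sf2, sn2, X, y, Xq)$var
    expect_true(all(v_n1 <= v_n + 1e-10))
  }
})

test_that("model serialization round-trips the hyperparameters", {
  set.seed(8)
  m <- gp_fit(matrix(rnorm(12), 6, 2), rnorm(6), seed = 1)
  doc <- jsonlite::fromJSON(gp_to_json(m))
  expect_equal(doc$hyperparams$l, m$hyperparams$l)
  expect_equal(doc$n_train, 6)
})
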