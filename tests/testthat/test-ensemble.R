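
test_that("a one-phase ensemble is exactly the global model", {
  set.seed(52)
  X <- matrix(rnorm(40), 20, 2); y <- rnorm(20)
  em <- fit_ensemble(X, y, K = 1, seed = 7)
  gl <- fit_gpr_sensor(X, y, seed = 7)
  Xq <- matrix(rnorm(12), 6, 2)
  expect_equal(predict(em, Xq)$mean, predict(gl, Xq)$mean, tolerance = 1e-12)
  expect_identical(em$local_models[[1]]$hyperparams, gl$model$hyperparams)
})

test_that("phase partition recovers the generating regimes", {
  d <- three_regime_data()
  em <- fit_ensemble(d$X, d$y, K = 3, seed = 1)
  expect_equal(em$K, 3)
  expect_gt(adjusted_rand_index(em$assignments, d$regime), 0.9)
  # same seed, same model
  em2 <- fit_ensemble(d$X, d$y, K = 3, seed = 1)
  expect_identical(em$assignments, em2$assignments)
  expect_equal(predict(em, d$X[1:5, ])$mean, predict(em2, d$X[1:5, ])$mean)
})

test_that("fusion weights form a simplex and concentrate at phase centers", {
  d <- three_regime_data()
  em <- fit_ensemble(d$X, d$y, K = 3, seed = 1)
  set.seed(53)
  Xq <- rbind(matrix(rnorm(40, sd = 3), 20, 2), d$X[1:10, ])
  pr <- predict(em, Xq)
  expect_equal(rowSums(pr$weights), rep(1, nrow(Xq)), tolerance = 1e-12)
  expect_true(all(pr$weights >= 0))
  # deep inside a phase the fused value is that phase's local value
  centers <- t(vapply(1:3, function(g)
    colMeans(d$X[em$assignments == g, ]), numeric(2)))
  pc <- predict(em, centers)
  for (g in 1:3)
    expect_equal(pc$mean[g], pc$local_mean[g, g], tolerance = 1e-6)
})

test_that("fused prediction equals a from-scratch weighted-sum oracle", {
  d <- three_regime_data(n_per = 25)
  em <- fit_ensemble(d$X, d$y, K = 3, seed = 2)
  set.seed(54)
  Xq <- matrix(rnorm(20, sd = 4), 10, 2)
  pr <- predict(em, Xq)
  # oracle: dense densities -> posterior weights; dense GP algebra per
  # local model; weighted sum; all outside the package's code paths
  g <- em$gmm
  dens <- vapply(seq_len(g$K), function(k) {
    S <- g$covariances[, , k]
    vapply(seq_len(nrow(Xq)), function(i) {
      dv <- Xq[i, ] - g$means[k, ]
      exp(-0.5 * drop(t(dv) %*% solve(S) %*% dv)) /
        sqrt((2 * pi)^2 * det(S))
    }, numeric(1))
  }, numeric(nrow(Xq)))
  W <- sweep(dens, 2, g$weights, "*")
  W <- W / rowSums(W)
  Wg <- vapply(seq_len(em$K), function(gg)
    rowSums(W[, em$group_of == gg, drop = FALSE]), numeric(nrow(Xq)))
  M <- vapply(seq_len(em$K), function(gg) {
    mdl <- em$local_models[[gg]]
    h <- mdl$hyperparams
    dense_gp_predict(h$l, h$sigma_f2, h$sigma_n2,
                     mdl$X_train, mdl$y_train, Xq)$mean
  }, numeric(nrow(Xq)))
  oracle <- rowSums(Wg * M) * em$y_scale + em$y_center
  expect_equal(pr$mean, oracle, tolerance = 1e-8)
})

test_that("sparse phases are absorbed and keep their posterior mass", {
  set.seed(55)
  # fixed three-phase mixture; the third phase has too few labeled points
  params <- gmm_params(rep(1 / 3, 3), rbind(c(0, 0), c(9, 0), c(0, 9)),
                       array(diag(2), c(2, 2, 3)))
  X <- rbind(matrix(rnorm(40, sd = 0.5), 20, 2),
             sweep(matrix(rnorm(40, sd = 0.5), 20, 2), 2, c(9, 0), "+"),
             sweep(matrix(rnorm(4, sd = 0.5), 2, 2), 2, c(0, 9), "+"))
  y <- rnorm(42)
  em <- fit_ensemble(X, y, K = 3, seed = 1, X_phases = params)
  expect_equal(em$K, 2)                    # two labeled points cannot stand alone
  expect_length(em$local_models, 2)
  expect_length(em$group_of, 3)            # all three components still weigh in
  pr <- predict(em, rbind(c(0, 9), c(0, 0)))
  expect_equal(rowSums(pr$weights), rep(1, 2), tolerance = 1e-12)
  # the absorbed phase's posterior mass lands on its absorber, not nowhere
  expect_gt(max(pr$weights[1, ]), 0.99)
})

test_that("a phase model from richer inputs can drive the partition", {
  d <- three_regime_data(n_per = 50)
  lab <- sort(c(sample(which(d$regime == 1), 4),
                sample(which(d$regime == 2), 12),
                sample(which(d$regime == 3), 12)))
  em <- fit_ensemble(d$X[lab, ], d$y[lab], K = 3, seed = 3, X_phases = d$X)
  expect_gt(adjusted_rand_index(em$assignments, d$regime[lab]), 0.9)
  # prefitted mixture parameters are accepted and reused verbatim
  g <- gmm_fit(d$X, 3, seed = 3)$params
  em2 <- fit_ensemble(d$X[lab, ], d$y[lab], K = 3, seed = 3, X_phases = g)
  expect_identical(em2$gmm, g)
})

test_that("variant tags map to their selection strategy and learner", {
  expect_identical(variant_tags(), c("GPR", "EGPR", "AL-GPR", "AL-EGPR"))
  expect_identical(alegpr:::variant_strategy("GPR"), "random")
  expect_identical(alegpr:::variant_strategy("AL-EGPR"), "active")
  expect_identical(alegpr:::variant_learner("AL-GPR"), "global")
  expect_identical(alegpr:::variant_learner("EGPR"), "ensemble")
  expect_error(alegpr:::variant_strategy("PLS"), "unknown")
})

test_that("too few labeled samples is a fit error", {
  expect_error(fit_ensemble(matrix(rnorm(4), 2, 2), rnorm(2), K = 2),
               "labeled samples")
})

test_that("model bundles survive a JSON round trip", {
  d <- three_regime_data(n_per = 20, seed = 56)
  Xq <- matrix(rnorm(20, sd = 3), 10, 2)
  em <- fit_ensemble(d$X, d$y, K = 3, seed = 1)
  f <- tempfile(fileext = ".json")
  model_to_json(em, f)
  expect_equal(predict(model_from_json(f), Xq)$mean, predict(em, Xq)$mean,
               tolerance = 1e-10)
  gl <- fit_gpr_sensor(d$X, d$y, seed = 1)
  model_to_json(gl, f)
  expect_equal(predict(model_from_json(f), Xq)$mean, predict(gl, Xq)$mean,
               tolerance = 1e-10)
  unlink(f)
})
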