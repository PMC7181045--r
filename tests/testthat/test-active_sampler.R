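# A hand-buildable 4-leaf tree: two tight pairs far apart, so the
# topology is ((1,2),(3,4)).
four_leaf_tree <- function() {
  build_hctree(matrix(c(0, 1, 10, 11), ncol = 1))
}

# state over a given tree with explicit quantile classes
quantile_state <- function(tree, y_init, n_classes = 2L, seed = 1L, ...) {
  init_sampler(tree, y_init = y_init, scheme = "quantile",
               n_classes = n_classes, seed = seed, ...)
}

test_that("quantile classes split at the frozen empirical quantiles", {
  qc <- quality_classes(c(1, 2, 3, 10, 11, 12), k_c = 2)
  expect_equal(qc$classes, c(1L, 1L, 1L, 2L, 2L, 2L))
  # edges frozen from one batch classify later values consistently
  qc2 <- quality_classes(c(0, 100), k_c = 2, edges = qc$edges)
  expect_equal(qc2$classes, c(1L, 2L))
  expect_warning(quality_classes(rep(3, 5), k_c = 3), "single-class")
})

test_that("node statistics reproduce the hand-computed confidence bounds", {
  tree <- four_leaf_tree()
  st <- quantile_state(tree, y_init = c(0, 1), n_classes = 2,
                       pruning_size = 1)
  # label leaves 1, 2 as class A(1) and leaf 3 as class B(2); leaf 4 stays
  st <- update_node_stats(st, ids = c(1L, 2L, 3L), classes = c(1L, 1L, 2L))
  root <- tree$root
  p <- 2 / 3
  delta <- 1 / 3 + sqrt((1 - p) * p / 3)
  expect_equal(st$stats$p[root, 1], p)
  expect_equal(st$stats$d[root, 1], 1 - p)
  expect_equal(st$stats$delta[root, 1], delta)
  expect_equal(st$stats$lb[root, 1], max(p - delta, 0))
  expect_equal(st$stats$ub[root, 1], min(p + delta, 1))
  # the pure (1,2) node: p = 1, delta = 1/n
  v12 <- tree$parent[1]
  expect_equal(st$stats$p[v12, 1], 1)
  expect_equal(st$stats$lb[v12, 1], 0.5)
  expect_equal(st$stats$ub[v12, 1], 1)
  # unqueried leaf 4: vacuous bounds, no admissible class, error 1
  expect_equal(st$stats$lb[4, ], c(0, 0))
  expect_equal(st$stats$ub[4, ], c(1, 1))
  expect_false(any(st$stats$admissible[4, ]))
  expect_equal(node_error(st, 4)$error, 1)
})

test_that("admissibility implements the beta-competition rule", {
  tree <- four_leaf_tree()
  st <- quantile_state(tree, y_init = c(0, 1), n_classes = 2,
                       pruning_size = 1)
  st <- update_node_stats(st, ids = c(1L, 2L, 3L, 4L),
                          classes = c(1L, 1L, 1L, 2L))
  # internal consistency with the printed inequality at beta = 2
  for (v in seq_len(2 * tree$n - 1)) {
    if (st$stats$n_lab[v] == 0) next
    for (cc in 1:2) {
      rival <- 3 - cc
      want <- (1 - st$stats$lb[v, cc]) <
        st$beta * (1 - st$stats$ub[v, rival])
      expect_identical(node_admissible(st, v, cc), want)
    }
  }
  # a well-supported pure node admits its class and has zero error
  v12 <- tree$parent[1]
  expect_true(node_admissible(st, v12, 1))
  ne <- node_error(st, v12)
  expect_equal(ne$class, 1L)
  expect_equal(ne$error, 0)
})

test_that("refinement finds the zero-error pruning for a clean split", {
  tree <- four_leaf_tree()
  st <- quantile_state(tree, y_init = c(0, 1), n_classes = 2,
                       pruning_size = 1)
  st <- update_node_stats(st, ids = 1:4, classes = c(1L, 1L, 2L, 2L))
  expect_identical(st$pruning, tree$root)
  st <- refine_pruning(st)
  expect_setequal(st$pruning, c(tree$parent[1], tree$parent[3]))
  expect_equal(st$total_error, 0)
})

test_that("refinement attains the exhaustive minimum over refinements", {
  set.seed(41)
  for (r in 1:40) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    tree <- build_hctree(X)
    st <- quantile_state(tree, y_init = c(0, 0.5, 1), n_classes = 3,
                         pruning_size = 1)
    k <- sample(1:n, 1)
    ids <- sample(n, k)
    st <- update_node_stats(st, ids = ids,
                            classes = sample(1:3, k, replace = TRUE))
    st <- refine_pruning(st)
    w <- tree$n_leaves / tree$n
    oracle <- best_pruning_error(tree, tree$root, st$stats$err, w)
    expect_equal(st$total_error, oracle, tolerance = 1e-12)
    # result is an antichain covering all leaves exactly once
    leaves <- unlist(lapply(st$pruning, function(v) tree$leaf_sets[[v]]))
    expect_equal(sort(leaves), 1:n)
  }
})

test_that("weighted refinement error never increases across sweeps", {
  set.seed(42)
  X <- matrix(rnorm(60), 30, 2)
  tree <- build_hctree(X)
  st <- quantile_state(tree, y_init = c(0, 0.5, 1), n_classes = 3,
                       pruning_size = 6)
  st <- update_node_stats(st, ids = sample(30, 12),
                          classes = sample(1:3, 12, replace = TRUE))
  e0 <- sum((tree$n_leaves / tree$n * st$stats$err)[st$pruning])
  st1 <- refine_pruning(st)
  expect_lte(st1$total_error, e0 + 1e-12)
  st2 <- refine_pruning(st1)
  expect_equal(st2$total_error, st1$total_error)  # fixpoint
})

test_that("selection drains untouched regions before confident ones", {
  tree <- four_leaf_tree()
  st <- quantile_state(tree, y_init = c(0, 1), n_classes = 2,
                       pruning_size = 2)
  # the (1,2) subtree is fully labeled; (3,4) untouched
  st <- update_node_stats(st, ids = c(1L, 2L), classes = c(1L, 1L))
  sel <- select_batch(st, 2)
  expect_setequal(sel$ids, c(3L, 4L))
  # a further request finds the pool exhausted... of unqueried leaves
  st2 <- update_node_stats(sel$state, sel$ids, classes = c(2L, 2L))
  sel2 <- select_batch(st2, 1)
  expect_length(sel2$ids, 0)
  expect_true(sel2$exhausted)
})

test_that("batches are reproducible and never repeat a sample", {
  set.seed(43)
  X <- matrix(rnorm(80), 40, 2)
  tree <- build_hctree(X)
  mk <- function() quantile_state(tree, y_init = c(0, 0.5, 1),
                                  n_classes = 3, pruning_size = 10,
                                  seed = 99)
  s1 <- select_batch(mk(), 15)
  s2 <- select_batch(mk(), 15)
  expect_identical(s1$ids, s2$ids)
  expect_equal(anyDuplicated(s1$ids), 0)
  # ns larger than the pool returns the whole pool
  s3 <- select_batch(mk(), 100)
  expect_setequal(s3$ids, 1:40)
  expect_true(s3$exhausted)
})

test_that("iterations move samples one way and ns = 0 is a no-op", {
  set.seed(44)
  X <- matrix(rnorm(120), 60, 2)
  y_pool <- rnorm(60)
  tree <- build_hctree(X)
  oracle <- function(ids) y_pool[ids]
  st <- init_sampler(tree, X_pool = X, n_classes = 3, pruning_size = 15,
                     seed = 5)
  r0 <- al_iteration(st, oracle, 0)
  expect_identical(r0$state$queried, st$queried)
  queried <- integer(0)
  for (it in 1:6) {
    res <- al_iteration(st, oracle, 10)
    st <- res$state
    expect_length(intersect(res$ids, queried), 0)
    queried <- c(queried, res$ids)
  }
  expect_setequal(queried, 1:60)      # 6 x 10 drains the 60-sample pool
  res <- al_iteration(st, oracle, 10)
  expect_length(res$ids, 0)
  expect_true(res$exhausted)
})

test_that("an oracle failure leaves the caller's state untouched", {
  set.seed(45)
  X <- matrix(rnorm(40), 20, 2)
  tree <- build_hctree(X)
  st <- init_sampler(tree, X_pool = X, n_classes = 2, pruning_size = 5,
                     seed = 3)
  bad <- function(ids) stop("lab is closed")
  expect_error(al_iteration(st, bad, 5), "lab is closed")
  expect_identical(sum(st$queried), 0L)
})

test_that("confidence half-widths shrink as subtree label counts grow", {
  set.seed(46)
  p_true <- 0.7
  shrink <- replicate(200, {
    lab_small <- rbinom(5, 1, p_true)
    lab_big <- c(lab_small, rbinom(20, 1, p_true))
    dl <- function(lab) {
      n <- length(lab); p <- mean(lab)
      1 / n + sqrt((1 - p) * p / n)
    }
    dl(lab_big) < dl(lab_small)
  })
  expect_gt(mean(shrink), 0.95)
})
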