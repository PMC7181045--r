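# Independent oracles used across tests. Everything here is written in
# plain dense linear algebra / exhaustive enumeration, deliberately
# avoiding the package's own computational paths.

# --- dense GP oracle -------------------------------------------------

dense_kernel_matrix <- function(X1, X2, l, sf2, sn2, noise_diag = FALSE) {
  K <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1)))
    for (j in seq_len(nrow(X2)))
      K[i, j] <- sf2 * exp(-sum((X1[i, ] - X2[j, ])^2) / (2 * l^2))
  if (noise_diag) K <- K + diag(sn2, nrow(X1))
  K
}

dense_gp_lml <- function(l, sf2, sn2, X, y) {
  K <- dense_kernel_matrix(X, X, l, sf2, sn2, noise_diag = TRUE)
  n <- length(y)
  -n / 2 * log(2 * pi) - 0.5 * determinant(K, logarithm = TRUE)$modulus -
    0.5 * drop(t(y) %*% solve(K) %*% y)
}

dense_gp_predict <- function(l, sf2, sn2, X, y, Xq) {
  K <- dense_kernel_matrix(X, X, l, sf2, sn2, noise_diag = TRUE)
  Kt <- dense_kernel_matrix(X, Xq, l, sf2, sn2)
  Kinv <- solve(K)
  mu <- drop(t(Kt) %*% Kinv %*% y)
  var <- (sf2 + sn2) - diag(t(Kt) %*% Kinv %*% Kt)
  list(mean = mu, var = pmax(var, 0))
}

# draw a GP sample with known hyperparameters
sample_gp <- function(X, l, sf2, sn2) {
  K <- dense_kernel_matrix(X, X, l, sf2, sn2, noise_diag = TRUE)
  drop(t(chol(K + diag(1e-10, nrow(X)))) %*% stats::rnorm(nrow(X)))
}

# --- Ward agglomeration oracle (direct merged-cluster ESS) -----------

ess_of <- function(M) {
  ctr <- colMeans(M)
  sum(sweep(M, 2L, ctr)^2)
}

# O(n^3) greedy agglomeration working on explicit point sets; merge cost
# is the increase in total ESS; ties broken by the smallest
# (min id left, min id right) pair.
ward_oracle <- function(X, ids = seq_len(nrow(X))) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        ca <- clusters[[a]]; cb <- clusters[[b]]
        inc <- ess_of(X[c(ca, cb), , drop = FALSE]) -
          ess_of(X[ca, , drop = FALSE]) - ess_of(X[cb, , drop = FALSE])
        key <- c(inc,
                 min(min(ids[ca]), min(ids[cb])),
                 max(min(ids[ca]), min(ids[cb])))
        if (is.null(best) ||
            key[1L] < best$key[1L] - 1e-12 ||
            (abs(key[1L] - best$key[1L]) <= 1e-12 &&
             (key[2L] < best$key[2L] ||
              (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    ca <- clusters[[best$a]]; cb <- clusters[[best$b]]
    merges[[length(merges) + 1L]] <- sort(ids[c(ca, cb)])
    heights <- c(heights, best$key[1L])
    clusters[[best$a]] <- c(ca, cb)
    clusters[[best$b]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# merged leaf-id sets of a package tree, in merge order
tree_merge_sets <- function(tree) {
  lapply(seq_len(tree$n - 1L), function(s)
    sort(tree$leaf_ids[tree$leaf_sets[[tree$n + s]]]))
}

# --- pruning enumeration oracle --------------------------------------

# minimum weighted error over ALL prunings refining {v}, by recursion
best_pruning_error <- function(tree, v, err, w) {
  own <- w[v] * err[v]
  if (v <= tree$n) return(own)
  ch <- tree$children[v, ]
  min(own, best_pruning_error(tree, ch[1L], err, w) +
        best_pruning_error(tree, ch[2L], err, w))
}

# --- misc -------------------------------------------------------------

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# phase index of global sample ids under the default generator recipe
phase_of_ids <- function(ids, params = kinetic_params()) {
  t <- (ids - 1) * params$dt
  findInterval(t, params$feed_times)
}

# small deterministic dataset for data-model tests
toy_dataset <- function(n = 10L, m = 3L, seed = 42L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * m), n, m)
  colnames(X) <- paste0("u", seq_len(m))
  process_dataset(X, y = seq_len(n) / 10)
}

# y with three distinct regimes over three input clusters
three_regime_data <- function(n_per = 40, seed = 51) {
  set.seed(seed)
  mu <- rbind(c(0, 0), c(8, 0), c(0, 8))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * 2, sd = 0.7), n_per, 2), 2, mu[k, ], "+")))
  regime <- rep(1:3, each = n_per)
  y <- c(0.2 * X[regime == 1, 1],
         3 + sin(X[regime == 2, 1]),
         -2 + 0.5 * X[regime == 3, 2]) + rnorm(3 * n_per, sd = 0.05)
  list(X = X, y = y, regime = regime)
}
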