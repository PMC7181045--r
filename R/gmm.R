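#' Gaussian mixture parameters
#'
#' @param weights mixing proportions (sum to 1).
#' @param means K x m matrix of component means.
#' @param covariances m x m x K array of symmetric positive-definite
#'   component covariances.
#' @return an object of class \code{gmm_params}.
#' @export
gmm_params <- function(weights, means, covariances) {
  means <- as.matrix(means)
  K <- length(weights)
  m <- ncol(means)
  if (nrow(means) != K) stop("means must have one row per component")
  if (is.matrix(covariances)) covariances <- array(covariances, c(m, m, 1L))
  if (!all(dim(covariances) == c(m, m, K)))
    stop("covariances must be an m x m x K array")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  structure(list(K = K, m = m, weights = as.numeric(weights),
                 means = means, covariances = covariances),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("gmm_params: K=%d components in %d dimensions; weights: %s\n",
              x$K, x$m, paste(sprintf("%.3f", x$weights), collapse = ", ")))
  invisible(x)
}

# Log multivariate normal density of rows of X under (mu, Sigma).
log_mvn_density <- function(X, mu, Sigma) {
  U <- tryCatch(chol(Sigma), error = function(e)
    stop("conditioning error: singular component covariance"))
  Z <- backsolve(U, t(X) - mu, transpose = TRUE)   # m x n
  -0.5 * (ncol(X) * log(2 * pi)) - sum(log(diag(U))) - 0.5 * colSums(Z^2)
}

#' Density of one mixture component
#'
#' Multivariate normal density \eqn{p(x \mid \mu_k, \Sigma_k)} of a single
#' Gaussian component (without the mixing weight).
#'
#' @param x numeric vector (one point) or matrix of points (rows).
#' @param k component index.
#' @param params a [gmm_params()] object.
#' @param log return the log density.
#' @return density value(s).
#' @export
gmm_component_density <- function(x, k, params, log = FALSE) {
  if (k < 1L || k > params$K) stop("invalid component index")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != params$m) stop("dimension mismatch")
  ld <- log_mvn_density(X, params$means[k, ], params$covariances[, , k])
  if (log) ld else exp(ld)
}

# n x K matrix of log(pi_k) + log N(x | mu_k, Sigma_k).
gmm_log_joint <- function(params, X) {
  lj <- vapply(seq_len(params$K), function(k)
    log(params$weights[k]) +
      log_mvn_density(X, params$means[k, ], params$covariances[, , k]),
    numeric(nrow(X)))
  matrix(lj, nrow = nrow(X))
}

#' Log-likelihood of data under a Gaussian mixture
#'
#' @param params a [gmm_params()] object.
#' @param X data matrix.
#' @return total log-likelihood (natural log).
#' @export
gmm_loglik <- function(params, X) {
  X <- as.matrix(X)
  sum(row_logsumexp(gmm_log_joint(params, X)))
}

#' Posterior responsibilities of mixture components
#'
#' \eqn{p(C_k \mid x, \Xi) = \pi_k p(x \mid \theta_k) /
#' \sum_j \pi_j p(x \mid \theta_j)}, evaluated in log space for
#' numerical stability; rows sum to one.
#'
#' @param params a [gmm_params()] object.
#' @param X data matrix.
#' @return n x K matrix of responsibilities.
#' @export
gmm_responsibilities <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != params$m) stop("dimension mismatch")
  lj <- gmm_log_joint(params, X)
  exp(lj - row_logsumexp(lj))
}

# k-means++-style seeding: first center uniform, then proportional to
# squared distance to the nearest chosen center. Caller controls the seed.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = p)
      centers[k, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ])^2))
    }
  }
  centers
}

# Guard a covariance estimate: symmetrize, then add a trace-scaled ridge
# only if the matrix is not numerically positive definite.
guard_cov <- function(S, m) {
  S <- (S + t(S)) / 2
  base <- max(sum(diag(S)) / m, 1e-12)
  for (t in c(0, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2)) {
    Sj <- S + diag(t * base, m)
    ok <- tryCatch({ chol(Sj); TRUE }, error = function(e) FALSE)
    if (ok) return(Sj)
  }
  S + diag(base, m)
}

em_single_run <- function(X, K, seed, max_iter, tol) {
  n <- nrow(X); m <- ncol(X)
  mu <- with_seed(seed, kmeanspp_centers(X, K))
  pooled <- guard_cov(stats::cov(X) * (n - 1) / n, m)
  Sigma <- array(pooled, c(m, m, K))
  w <- rep(1 / K, K)
  params <- gmm_params(w, mu, Sigma)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lj <- gmm_log_joint(params, X)
    lse <- row_logsumexp(lj)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    R <- exp(lj - lse)                       # E step
    Nk <- colSums(R)
    # a full-covariance component needs at least m+1 points of support;
    # below that the likelihood is unbounded and the run is rejected
    if (any(Nk < m + 1)) return(NULL)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    w <- Nk / n                              # M step
    mu <- crossprod(R, X) / Nk
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, mu[k, ])
      Sigma[, , k] <- guard_cov(crossprod(Xc * R[, k], Xc) / Nk[k], m)
    }
    params <- gmm_params(w, mu, Sigma)
  }
  list(params = params,
       trace = list(loglik = ll_trace, converged = converged,
                    iterations = length(ll_trace)),
       loglik = ll_trace[length(ll_trace)])
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Standard EM with log-space responsibilities (E step) and closed-form
#' weight/mean/covariance updates (M step, MLE denominators). Means are
#' seeded k-means++-style, covariances start at the pooled covariance.
#' Several seeded restarts are run and the best log-likelihood returned.
#' A restart in which any component's responsibility mass falls below
#' m + 1 points is discarded: such a component cannot support a full
#' covariance and its likelihood contribution is unbounded (the classic
#' mixture degeneracy), so accepting it would make criteria like BIC
#' meaningless. If every restart degenerates the fit fails.
#'
#' @param X data matrix (n x m), n >= K.
#' @param K number of components.
#' @param seed integer seed (restart r uses seed + 1000*(r-1)).
#' @param n_restarts number of EM restarts.
#' @param max_iter EM iteration cap.
#' @param tol convergence threshold on the log-likelihood gain.
#' @return list with elements \code{params} ([gmm_params()]) and
#'   \code{trace} (per-iteration log-likelihood, non-decreasing;
#'   convergence flag; iterations used).
#' @export
gmm_fit <- function(X, K, seed = 1L, n_restarts = 5L,
                    max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (K < 1L) stop("K must be at least 1")
  if (n < K) stop("need at least K data points (n = ", n, ", K = ", K, ")")
  if (!all(is.finite(X))) stop("X contains non-finite entries")

  if (K == 1L) {
    mu <- matrix(colMeans(X), 1L)
    Sigma <- array(guard_cov(stats::cov(X) * (n - 1) / n, ncol(X)),
                   c(ncol(X), ncol(X), 1L))
    params <- gmm_params(1, mu, Sigma)
    ll <- gmm_loglik(params, X)
    return(list(params = params,
                trace = list(loglik = ll, converged = TRUE, iterations = 1L),
                loglik = ll))
  }

  best <- NULL
  attempts <- 0L
  r <- 0L
  good_runs <- 0L
  while (good_runs < n_restarts && attempts < n_restarts + 10L) {
    run <- em_single_run(X, K, seed + 1000L * r, max_iter, tol)
    r <- r + 1L
    attempts <- attempts + 1L
    if (is.null(run)) next
    good_runs <- good_runs + 1L
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best))
    stop("EM failed: every restart produced a degenerate component (K = ",
         K, ")")
  best
}

#' Bayesian information criterion for a fitted mixture
#'
#' The criterion used for component-number selection is
#' \deqn{\mathrm{BIC} = -2\log L(X \mid \Xi) + 3K\log N,}
#' i.e. a penalty of \eqn{3K\log N} regardless of input dimension; the
#' conventional free-parameter-count penalty is available behind
#' \code{penalty = "free-params"} but is not the default (see the methods
#' vignette for the discussion).
#'
#' @param params a [gmm_params()] object fitted on \code{X}.
#' @param X data matrix.
#' @param penalty \code{"3K"} (default) or \code{"free-params"}.
#' @return BIC value (lower is better).
#' @export
gmm_bic <- function(params, X, penalty = c("3K", "free-params")) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  N <- nrow(X)
  ll <- gmm_loglik(params, X)
  pen <- if (penalty == "3K") {
    3 * params$K * log(N)
  } else {
    m <- params$m
    (params$K - 1 + params$K * m + params$K * m * (m + 1) / 2) * log(N)
  }
  -2 * ll + pen
}

#' Select the number of mixture components by BIC
#'
#' Fits mixtures for each candidate K over several seeds and picks the K
#' minimizing the mean BIC; ties break toward smaller K (parsimony).
#' Candidates whose fits fail for every seed are skipped and recorded.
#'
#' Selection defaults to the free-parameter-count penalty: under the
#' flat \code{"3K"} penalty the criterion is not a valid model-selection
#' rule for full-covariance mixtures in more than a few dimensions — the
#' likelihood gain of splitting any non-Gaussian cluster outgrows the
#' penalty, so the argmin sits at the largest candidate for essentially
#' any continuous-process data (see the methods vignette). The flat
#' penalty remains available for reporting the criterion value itself.
#'
#' @param X data matrix.
#' @param k_range candidate component counts.
#' @param seeds integer seeds (one fit per seed per K).
#' @param penalty BIC penalty used for selection (see [gmm_bic()]).
#' @param ... passed on to [gmm_fit()].
#' @return list with \code{k} (selected count) and \code{table}
#'   (data frame of per-K mean/min/max BIC and failure counts).
#' @export
gmm_select_k <- function(X, k_range = 1:6, seeds = 1:5,
                         penalty = "free-params", ...) {
  X <- as.matrix(X)
  rows <- lapply(k_range, function(K) {
    bics <- vapply(seeds, function(s) {
      fit <- tryCatch(gmm_fit(X, K, seed = s, ...), error = function(e) NULL)
      if (is.null(fit)) NA_real_ else gmm_bic(fit$params, X, penalty = penalty)
    }, numeric(1L))
    data.frame(K = K, mean_bic = mean(bics, na.rm = TRUE),
               sd_bic = stats::sd(bics[!is.na(bics)]),
               n_failed = sum(is.na(bics)))
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$mean_bic)
  if (!any(ok)) stop("all candidate component counts failed to fit")
  cand <- tab[ok, ]
  k_star <- cand$K[which.min(cand$mean_bic)]   # which.min: first (smallest K) on ties
  list(k = k_star, table = tab)
}

#' Hard component assignment
#'
#' Argmax-responsibility component per row; ties break toward the lower
#' component index.
#'
#' @param params a [gmm_params()] object.
#' @param X data matrix.
#' @return integer component labels (1..K).
#' @export
gmm_hard_assign <- function(params, X) {
  R <- gmm_responsibilities(params, X)
  max.col(R, ties.method = "first")
}

#' Serialize mixture parameters to JSON
#'
#' @param params a [gmm_params()] object.
#' @param path optional output file.
#' @return the JSON string, invisibly if written to a file.
#' @export
gmm_to_json <- function(params, path = NULL) {
  doc <- list(K = params$K, m = params$m, weights = params$weights,
              means = params$means,
              covariances = lapply(seq_len(params$K), function(k)
                params$covariances[, , k]))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
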