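#' Gaussian process hyperparameters
#'
#' The squared-exponential kernel used throughout is
#' \deqn{k(x_i, x_j) = \sigma_f^2 \exp(-\|x_i - x_j\|^2 / (2 l^2))
#'       + \delta_{ij}\sigma_n^2,}
#' with a shared isotropic length-scale \eqn{l}, signal variance
#' \eqn{\sigma_f^2} and noise variance \eqn{\sigma_n^2}; the Kronecker
#' term acts on sample index, not location.
#'
#' @param l length-scale (> 0).
#' @param sigma_f2 signal variance (> 0).
#' @param sigma_n2 noise variance (>= 0).
#' @return an object of class \code{gp_hyperparams}.
#' @export
gp_hyperparams <- function(l, sigma_f2, sigma_n2) {
  vals <- c(l = l, sigma_f2 = sigma_f2, sigma_n2 = sigma_n2)
  if (!all(is.finite(vals))) stop("hyperparameters must be finite")
  if (l <= 0) stop("length-scale l must be strictly positive")
  if (sigma_f2 <= 0) stop("signal variance sigma_f2 must be strictly positive")
  if (sigma_n2 < 0) stop("noise variance sigma_n2 must be non-negative")
  structure(list(l = l, sigma_f2 = sigma_f2, sigma_n2 = sigma_n2),
            class = "gp_hyperparams")
}

# Squared Euclidean distances between the rows of two matrices.
sq_dist <- function(X1, X2 = X1) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  d <- matrix(rowSums(X1^2), n1, n2) +
    matrix(rowSums(X2^2), n1, n2, byrow = TRUE) -
    2 * tcrossprod(X1, X2)
  d[d < 0] <- 0
  d
}

#' Evaluate the squared-exponential kernel for one pair of points
#'
#' @param xi,xj numeric vectors of equal length.
#' @param hyp a [gp_hyperparams()] set.
#' @param same_index \code{TRUE} if xi and xj are the same training sample
#'   (adds the \eqn{\sigma_n^2} Kronecker term).
#' @return kernel value (scalar).
#' @export
gp_kernel <- function(xi, xj, hyp, same_index = FALSE) {
  if (length(xi) != length(xj)) stop("dimension mismatch between xi and xj")
  if (hyp$l <= 0) stop("length-scale l must be strictly positive")
  hyp$sigma_f2 * exp(-sum((xi - xj)^2) / (2 * hyp$l^2)) +
    if (same_index) hyp$sigma_n2 else 0
}

# Full kernel matrices; noise on the diagonal only when X2 is absent
# (training covariance K), never in cross-covariances.
gp_kernel_matrix <- function(X1, X2 = NULL, hyp) {
  if (is.null(X2)) {
    K <- hyp$sigma_f2 * exp(-sq_dist(X1) / (2 * hyp$l^2))
    K + diag(hyp$sigma_n2, nrow(X1))
  } else {
    hyp$sigma_f2 * exp(-sq_dist(X1, X2) / (2 * hyp$l^2))
  }
}

# Cholesky with a jitter ladder for nearly singular covariances.
jitter_chol <- function(K, ladder = c(0, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6)) {
  for (j in ladder) {
    U <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = j))
  }
  stop("conditioning error: covariance not positive definite after max jitter")
}

#' Log marginal likelihood of a GP regression model
#'
#' \deqn{\log p(y \mid X) = -\tfrac{n}{2}\log 2\pi
#'       - \tfrac12 \log\det K - \tfrac12 y^\top K^{-1} y,}
#' computed through a Cholesky factorization of \eqn{K} (with a small
#' jitter ladder on failure). Optionally returns the gradient with
#' respect to \eqn{(\log l, \log\sigma_f^2, \log\sigma_n^2)} for the
#' quasi-Newton fit.
#'
#' @param hyp a [gp_hyperparams()] set.
#' @param X training inputs (matrix).
#' @param y training targets (vector).
#' @param grad also compute the gradient (attached as attribute
#'   \code{"gradient"}).
#' @return the log marginal likelihood (scalar).
#' @export
gp_log_marginal <- function(hyp, X, y, grad = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X and y are not conformable")
  sqd <- sq_dist(X)
  Kse <- hyp$sigma_f2 * exp(-sqd / (2 * hyp$l^2))
  K <- Kse + diag(hyp$sigma_n2, n)
  ch <- jitter_chol(K)
  U <- ch$U
  alpha <- backsolve(U, backsolve(U, y, transpose = TRUE))
  ll <- -n / 2 * log(2 * pi) - sum(log(diag(U))) - sum(y * alpha) / 2
  if (grad) {
    Kinv <- chol2inv(U)
    A <- tcrossprod(alpha) - Kinv
    g <- c(
      log_l        = sum(A * (Kse * sqd / hyp$l^2)) / 2,
      log_sigma_f2 = sum(A * Kse) / 2,
      log_sigma_n2 = sum(diag(A)) * hyp$sigma_n2 / 2
    )
    attr(ll, "gradient") <- g
  }
  ll
}

#' Fit a GP regression model by marginal-likelihood maximization
#'
#' Quasi-Newton (L-BFGS-B) optimization of the log marginal likelihood in
#' \eqn{(\log l, \log\sigma_f^2, \log\sigma_n^2)}, restarted from a
#' moments-based start plus seeded log-uniform draws in
#' \eqn{[10^{-2}, 10^{2}]}; the best converged restart wins. The marginal
#' likelihood surface is multimodal, hence the restarts.
#'
#' @param X training inputs (n x m matrix).
#' @param y training targets (length n).
#' @param restarts number of optimizer starts.
#' @param seed integer seed for the random starts.
#' @param maxit optimizer iteration cap per start.
#' @return an object of class \code{gp_model} holding the hyperparameters,
#'   training data, cached Cholesky factor and \eqn{K^{-1} y}.
#' @export
gp_fit <- function(X, y, restarts = 5L, seed = 1L, maxit = 200L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X and y are not conformable")
  if (n < 1L) stop("need at least one training sample")

  vy <- if (n > 1L) stats::var(y) else 1
  if (!is.finite(vy) || vy <= 0) vy <- 1e-4
  med_d <- if (n > 1L) stats::median(sqrt(sq_dist(X)[upper.tri(diag(n))])) else 1
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  starts <- list(log(c(med_d, vy, 0.1 * vy + 1e-6)))
  if (restarts > 1L) {
    extra <- with_seed(seed, replicate(restarts - 1L,
      stats::runif(3L, log(1e-2), log(1e2)), simplify = FALSE))
    starts <- c(starts, extra)
  }

  lower <- log(c(1e-6, 1e-8, 1e-10))
  upper <- log(c(1e6, 1e8, 1e6))
  negll <- function(p) {
    h <- gp_hyperparams(exp(p[1L]), exp(p[2L]), exp(p[3L]))
    -as.numeric(gp_log_marginal(h, X, y))
  }
  negll_gr <- function(p) {
    h <- gp_hyperparams(exp(p[1L]), exp(p[2L]), exp(p[3L]))
    -attr(gp_log_marginal(h, X, y, grad = TRUE), "gradient")
  }

  best <- NULL
  diagnostics <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper), negll, negll_gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("fit error: no optimizer start converged (",
         paste(unique(diagnostics), collapse = "; "), ")")

  hyp <- gp_hyperparams(exp(best$par[1L]), exp(best$par[2L]), exp(best$par[3L]))
  K <- gp_kernel_matrix(X, hyp = hyp)
  ch <- jitter_chol(K)
  alpha <- backsolve(ch$U, backsolve(ch$U, y, transpose = TRUE))
  structure(list(hyperparams = hyp, X_train = X, y_train = y,
                 U = ch$U, alpha = alpha, jitter = ch$jitter,
                 log_marginal = -best$value),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "gp_model: n=%d, m=%d | l=%.4g, sigma_f2=%.4g, sigma_n2=%.4g | logML=%.4f\n",
    nrow(x$X_train), ncol(x$X_train), x$hyperparams$l,
    x$hyperparams$sigma_f2, x$hyperparams$sigma_n2, x$log_marginal))
  invisible(x)
}

#' Posterior prediction from a fitted GP model
#'
#' Posterior mean \eqn{k_t^\top K^{-1} y} and variance
#' \eqn{k(x_t,x_t) - k_t^\top K^{-1} k_t} per query point. The prior
#' variance \eqn{k(x_t,x_t)} includes the noise term
#' \eqn{\sigma_n^2} by default (set \code{include_noise = FALSE} for the
#' latent-function variance). Tiny negative variances from round-off are
#' clamped to zero.
#'
#' @param object a [gp_fit()] model.
#' @param Xq query inputs (matrix, same dimension as training inputs).
#' @param include_noise include \eqn{\sigma_n^2} in the predictive variance.
#' @param ... unused.
#' @return list with numeric vectors \code{mean} and \code{var}.
#' @export
predict.gp_model <- function(object, Xq, include_noise = TRUE, ...) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != ncol(object$X_train))
    stop("dimension mismatch: query has ", ncol(Xq), " columns, model has ",
         ncol(object$X_train))
  h <- object$hyperparams
  Kt <- gp_kernel_matrix(object$X_train, Xq, hyp = h)   # n x q
  mu <- drop(crossprod(Kt, object$alpha))
  v <- backsolve(object$U, Kt, transpose = TRUE)
  kss <- h$sigma_f2 + if (include_noise) h$sigma_n2 else 0
  var <- pmax(kss - colSums(v^2), 0)
  list(mean = mu, var = var)
}

#' Serialize a GP model to JSON
#'
#' @param model a [gp_fit()] model.
#' @param path optional output file; if missing, the JSON string is returned.
#' @return the JSON string, invisibly if written to a file.
#' @export
gp_to_json <- function(model, path = NULL) {
  doc <- list(
    hyperparams = unclass(model$hyperparams),
    log_marginal = model$log_marginal,
    n_train = nrow(model$X_train),
    X_train = model$X_train,
    y_train = model$y_train
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
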