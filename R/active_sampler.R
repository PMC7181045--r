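#' Derive discrete classes from labeled quality values
#'
#' The hierarchical sampler reasons about class purity of tree nodes, but
#' the soft-sensing target is continuous; quality values are therefore
#' discretized. The default scheme cuts the labeled target at its
#' empirical quantiles into \code{k_c} bins (3 by default, mirroring the
#' three physiological phases); the alternative assigns the hard GMM
#' component of each sample. Bin edges are frozen from the initial
#' labeled set so later queries never shift earlier class labels.
#'
#' @param y labeled target values.
#' @param scheme \code{"quantile"} or \code{"gmm"}.
#' @param k_c number of quantile bins (>= 2).
#' @param edges previously frozen bin edges (quantile scheme); computed
#'   from \code{y} when \code{NULL}.
#' @param gmm_params fitted [gmm_params()] (gmm scheme).
#' @param X inputs of the labeled samples (gmm scheme).
#' @return list with integer \code{classes} (1-based), the \code{edges}
#'   used, and \code{n_classes}.
#' @export
quality_classes <- function(y, scheme = c("quantile", "gmm"), k_c = 3L,
                            edges = NULL, gmm_params = NULL, X = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "gmm") {
    if (is.null(gmm_params) || is.null(X))
      stop("gmm scheme needs gmm_params and X")
    return(list(classes = gmm_hard_assign(gmm_params, X), edges = NULL,
                n_classes = gmm_params$K))
  }
  if (k_c < 2L) stop("k_c must be at least 2")
  if (is.null(edges)) {
    if (length(unique(y)) == 1L) {
      warning("all labeled targets equal; single-class labeling")
      return(list(classes = rep(1L, length(y)), edges = numeric(0),
                  n_classes = 1L))
    }
    edges <- unique(stats::quantile(y, probs = seq_len(k_c - 1L) / k_c,
                                    names = FALSE))
  }
  classes <- findInterval(y, edges, left.open = TRUE) + 1L
  list(classes = as.integer(classes), edges = edges,
       n_classes = length(edges) + 1L)
}

#' Initialize the hierarchical sampling state
#'
#' Builds the working pruning of the tree, fixes the class scheme, and
#' seeds the sampler's private random stream. The tree spans only the
#' unlabeled pool.
#'
#' Two class schemes are supported. The default, \code{"gmm"}, fits a
#' mixture to the pool inputs once and freezes the hard component
#' assignment of every leaf as its class: classes are operating phases
#' of the process, so subtree purity means "this region belongs to one
#' phase" and the sampler spreads its budget across phases and their
#' boundaries. The \code{"quantile"} scheme bins the labeled target
#' instead (edges frozen from the initially labeled samples); because a
#' nonmonotone quality variable crosses every bin repeatedly along the
#' trajectory, target bins place class boundaries inside phases and the
#' sampler then spends much of its budget resolving bin edges rather
#' than covering the process — it is retained for data whose target is
#' monotone in the operating conditions (see the methods vignette).
#'
#' @param tree an [build_hctree()] tree over the pool.
#' @param X_pool pool inputs in tree-leaf order (\code{"gmm"} scheme).
#' @param y_init target values of the initially labeled samples
#'   (\code{"quantile"} scheme: used to freeze the bin edges).
#' @param scheme class scheme, \code{"gmm"} (default) or
#'   \code{"quantile"}.
#' @param n_classes number of classes (mixture components or target
#'   bins).
#' @param beta admissibility factor (> 1); the reference value is 2.
#' @param pruning_size size of the initial tree cut (capped at the leaf
#'   count).
#' @param seed integer seed (mixture fit and random descents).
#' @return an object of class \code{pruning_state}.
#' @export
init_sampler <- function(tree, X_pool = NULL, y_init = NULL,
                         scheme = c("gmm", "quantile"), n_classes = 3L,
                         beta = 2, pruning_size = 150L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (beta <= 1) stop("beta must be greater than 1")
  edges <- NULL
  leaf_class <- NULL
  if (scheme == "gmm") {
    if (is.null(X_pool)) stop("gmm scheme needs X_pool")
    if (nrow(X_pool) != tree$n) stop("X_pool must have one row per leaf")
    # pools too small for n_classes non-degenerate phases fall back to
    # fewer classes (a single class still samples, purely by coverage)
    K <- as.integer(n_classes)
    fit <- NULL
    while (K > 1L && is.null(fit)) {
      fit <- tryCatch(gmm_fit(as.matrix(X_pool), K, seed = seed),
                      error = function(e) NULL)
      if (is.null(fit)) K <- K - 1L
    }
    leaf_class <- if (is.null(fit)) rep(1L, tree$n) else
      gmm_hard_assign(fit$params, as.matrix(X_pool))
    n_classes <- max(K, 1L)
  } else {
    if (is.null(y_init)) stop("quantile scheme needs y_init")
    qc <- quality_classes(y_init, k_c = n_classes)
    edges <- qc$edges
    n_classes <- qc$n_classes
  }
  rng <- with_seed(seed, { stats::runif(1L); get_rng_state() })
  state <- structure(list(
    tree = tree,
    beta = beta,
    scheme = scheme,
    n_classes = n_classes,
    class_edges = edges,
    leaf_class = leaf_class,
    pruning = initial_pruning(tree, min(pruning_size, tree$n)),
    queried = rep(FALSE, tree$n),
    pending = rep(FALSE, tree$n),
    class_of = rep(NA_integer_, tree$n),
    stats = NULL,
    rng = rng,
    n_batches = 0L
  ), class = "pruning_state")
  update_node_stats(state)
}

#' @export
print.pruning_state <- function(x, ...) {
  cat(sprintf(
    "pruning_state: %d leaves (%d queried), pruning size %d, %d classes, beta=%g\n",
    x$tree$n, sum(x$queried), length(x$pruning), x$n_classes, x$beta))
  invisible(x)
}

#' Recompute per-node class statistics and confidence bounds
#'
#' For every tree node \eqn{v} with \eqn{n_v > 0} queried samples in its
#' subtree: class fractions \eqn{p_{v,c} = n_{v,c}/n_v}, the
#' generalization-bound half-width
#' \eqn{\Delta_{v,c} = 1/n_v + \sqrt{d_v\,p_{v,c}/n_v}} with impurity
#' \eqn{d_v = 1 - n_{v,c}/n_v} (so the radicand is the Wald term
#' \eqn{p(1-p)/n}), and bounds clamped to [0, 1]. The \eqn{1/n_v} term
#' is deliberately purity-independent: a subtree vouched for by a single
#' sample must stay wide open, otherwise exploration collapses (see the
#' methods vignette). Nodes without queried samples get vacuous bounds
#' [0, 1] for every class. Admissibility, best class and node error are
#' refreshed alongside (see [node_error()]).
#'
#' @param state a [init_sampler()] state.
#' @param ids sample ids newly queried (optional).
#' @param classes their integer class labels (1-based, same length).
#' @return the updated \code{pruning_state}.
#' @export
update_node_stats <- function(state, ids = NULL, classes = NULL) {
  tree <- state$tree
  if (!is.null(ids)) {
    leaves <- match(ids, tree$leaf_ids)
    if (anyNA(leaves)) stop("unknown sample id(s) for this tree")
    state$queried[leaves] <- TRUE
    state$pending[leaves] <- FALSE
    state$class_of[leaves] <- as.integer(classes)
  }

  n_nodes <- 2L * tree$n - 1L
  C <- state$n_classes
  counts <- matrix(0, n_nodes, C)
  qleaves <- which(state$queried)
  for (lf in qleaves) {
    cl <- state$class_of[lf]
    v <- lf
    while (!is.na(v)) {
      counts[v, cl] <- counts[v, cl] + 1
      v <- tree$parent[v]
    }
  }
  n_lab <- rowSums(counts)

  p <- counts / pmax(n_lab, 1)
  d <- 1 - p
  delta <- 1 / pmax(n_lab, 1) + sqrt(d * p / pmax(n_lab, 1))
  lb <- pmax(p - delta, 0)
  ub <- pmin(p + delta, 1)
  vac <- n_lab == 0
  p[vac, ] <- NA_real_
  lb[vac, ] <- 0
  ub[vac, ] <- 1

  # class c admissible at v iff (1 - lb_c) < beta * (1 - ub_c') for all c' != c
  adm <- matrix(FALSE, n_nodes, C)
  if (C == 1L) {
    adm[, 1L] <- TRUE                # no rivals: vacuously admissible
  } else {
    for (cc in seq_len(C)) {
      rivals <- setdiff(seq_len(C), cc)
      worst_rival <- if (length(rivals) == 1L) ub[, rivals] else
        apply(ub[, rivals, drop = FALSE], 1L, max)
      adm[, cc] <- (1 - lb[, cc]) < state$beta * (1 - worst_rival)
    }
  }
  adm[vac, ] <- FALSE

  best_class <- rep(NA_integer_, n_nodes)
  err <- rep(1, n_nodes)
  best_lb <- rep(0, n_nodes)
  has_adm <- which(rowSums(adm) > 0)
  for (v in has_adm) {
    cand <- which(adm[v, ])
    bc <- cand[which.max(p[v, cand])]   # ties -> lower class index
    best_class[v] <- bc
    err[v] <- 1 - p[v, bc]
    best_lb[v] <- lb[v, bc]
  }

  state$stats <- list(counts = counts, n_lab = n_lab, p = p, d = d,
                      delta = delta, lb = lb, ub = ub, admissible = adm,
                      best_class = best_class, err = err, best_lb = best_lb)
  state
}

#' Is a class admissible at a node?
#'
#' Class \eqn{c} is admissible at node \eqn{v} when committing to it
#' costs at most \eqn{\beta} times as much as committing to any rival:
#' \eqn{(1 - p^{LB}_{v,c}) < \beta (1 - p^{UB}_{v,c'})} for all
#' \eqn{c' \ne c}.
#'
#' @param state a state with refreshed statistics.
#' @param node node number.
#' @param class class index.
#' @return logical flag.
#' @export
node_admissible <- function(state, node, class) {
  state$stats$admissible[node, class]
}

#' Best class and classification error of a node
#'
#' Among the admissible classes the one with maximal class fraction is
#' chosen (ties to the lower index) and the node error is one minus that
#' fraction; a node with no admissible class has error 1.
#'
#' @param state a state with refreshed statistics.
#' @param node node number.
#' @return list with \code{class} (or \code{NA}) and \code{error}.
#' @export
node_error <- function(state, node) {
  list(class = state$stats$best_class[node],
       error = state$stats$err[node])
}

#' Refine the working pruning to the minimum-error antichain
#'
#' Replaces pruning nodes by descendants whenever that lowers the total
#' mass-weighted classification error
#' \eqn{\sum_v w_v \tilde\varepsilon_v}, \eqn{w_v =} subtree leaf count /
#' total leaves. Each current pruning node is resolved by the subtree
#' recursion \code{best(v) = min(w_v err_v, best(left) + best(right))}
#' (ties keep the coarser node), which is the fixpoint of parent-child
#' replacement against fully refined child subtrees and attains the
#' exhaustive minimum over all refinements. \code{weighted = FALSE}
#' reproduces the raw unweighted parent-vs-children comparison instead.
#'
#' @param state a state with refreshed statistics.
#' @param weighted use leaf-mass weights (default) or raw errors.
#' @return the updated state (fields \code{pruning},
#'   \code{total_error}).
#' @export
refine_pruning <- function(state, weighted = TRUE) {
  tree <- state$tree
  err <- state$stats$err
  w <- if (weighted) tree$n_leaves / tree$n else rep(1, length(err))

  best_nodes <- vector("list", 2L * tree$n - 1L)
  best_cost <- rep(NA_real_, 2L * tree$n - 1L)
  resolve <- function(v) {
    if (!is.na(best_cost[v])) return(best_cost[v])
    own <- w[v] * err[v]
    if (v <= tree$n) {
      best_cost[v] <<- own
      best_nodes[[v]] <<- v
      return(own)
    }
    ch <- tree$children[v, ]
    sub <- resolve(ch[1L]) + resolve(ch[2L])
    if (sub < own - 1e-12) {
      best_cost[v] <<- sub
      best_nodes[[v]] <<- c(best_nodes[[ch[1L]]], best_nodes[[ch[2L]]])
    } else {
      best_cost[v] <<- own
      best_nodes[[v]] <<- v
    }
    best_cost[v]
  }

  total <- 0
  new_pruning <- integer(0)
  for (v in state$pruning) {
    total <- total + resolve(v)
    new_pruning <- c(new_pruning, best_nodes[[v]])
  }
  state$pruning <- sort(new_pruning)
  state$total_error <- total
  state
}

# Unqueried (and not pending) leaf count under each node of a set.
unqueried_count <- function(state, nodes) {
  open <- !(state$queried | state$pending)
  vapply(nodes, function(v) sum(open[state$tree$leaf_sets[[v]]]), numeric(1L))
}

#' Select a batch of informative pool samples
#'
#' Repeats \code{ns} times (or until the pool is exhausted): take the
#' pruning node with the smallest lower confidence bound for its best
#' class (no admissible class counts as 0; ties are broken uniformly at
#' random from the sampler's seeded stream), then descend, choosing a child
#' with probability proportional to its unqueried leaf count, until an
#' unqueried leaf is reached. Nodes whose subtrees are fully queried are
#' skipped. Selected leaves are marked pending so one batch never
#' repeats a sample.
#'
#' @param state a [init_sampler()] state.
#' @param ns batch size.
#' @return list with elements \code{state} (updated), \code{ids}
#'   (selected sample ids, ordered), \code{paths} (node path per
#'   selection) and \code{exhausted} flag.
#' @export
select_batch <- function(state, ns) {
  tree <- state$tree
  old_rng <- get_rng_state()
  on.exit(set_rng_state(old_rng), add = TRUE)
  set_rng_state(state$rng)

  ids <- integer(0)
  paths <- list()
  exhausted <- FALSE
  for (i in seq_len(ns)) {
    ucount <- unqueried_count(state, state$pruning)
    open <- ucount > 0
    if (!any(open)) { exhausted <- TRUE; break }
    cand <- state$pruning[open]
    score <- state$stats$best_lb[cand]
    cand <- cand[score == min(score)]
    # minimal-lower-bound ties (early on most nodes tie at 0) go to the
    # node with the fewest queried samples, then at random with
    # probability proportional to subtree size: every stratum is visited
    # before any is revisited (stratified spread), and within a sweep
    # large strata are served first, matching the data mass when the
    # batch budget is smaller than the pruning
    if (length(cand) > 1L) {
      nq <- state$stats$n_lab[cand]
      cand <- cand[nq == min(nq)]
    }
    v <- if (length(cand) > 1L) {
      cand[[sample.int(length(cand), 1L, prob = tree$n_leaves[cand])]]
    } else cand[1L]
    path <- v
    while (v > tree$n) {
      ch <- tree$children[v, ]
      u <- unqueried_count(state, ch)
      v <- if (u[1L] == 0) ch[2L] else if (u[2L] == 0) ch[1L] else
        ch[1L + (stats::runif(1L) >= u[1L] / sum(u))]
      path <- c(path, v)
    }
    state$pending[v] <- TRUE
    ids <- c(ids, tree$leaf_ids[v])
    paths[[length(paths) + 1L]] <- path
  }
  state$rng <- get_rng_state()
  state$n_batches <- state$n_batches + 1L
  list(state = state, ids = ids, paths = paths,
       exhausted = exhausted || length(ids) < ns)
}

#' One active-learning iteration
#'
#' Selects a batch, queries the oracle for its labels, folds the new
#' labels into the node statistics (classes via the frozen bin edges)
#' and refines the pruning. The update is atomic: an oracle failure
#' leaves the caller's state untouched.
#'
#' @param state a [init_sampler()] state.
#' @param oracle a [make_oracle()] labeler (or any function mapping ids
#'   to target values).
#' @param ns batch size; \code{ns = 0} is a no-op.
#' @return list with the updated \code{state}, queried \code{ids}, their
#'   \code{y} values, the audit trace (\code{paths}: node path per
#'   selection; \code{pruning_size}; \code{total_error}) and the
#'   \code{exhausted} flag.
#' @export
al_iteration <- function(state, oracle, ns) {
  if (ns == 0L)
    return(list(state = state, ids = integer(0), y = numeric(0),
                exhausted = FALSE))
  sel <- select_batch(state, ns)
  if (length(sel$ids) == 0L)
    return(list(state = state, ids = integer(0), y = numeric(0),
                exhausted = TRUE))
  qfun <- if (inherits(oracle, "label_oracle")) oracle$query else oracle
  y <- qfun(sel$ids)
  if (length(y) != length(sel$ids) || !all(is.finite(y)))
    stop("oracle failure: invalid labels returned")
  cl <- if (state$scheme == "gmm") {
    state$leaf_class[match(sel$ids, state$tree$leaf_ids)]
  } else if (state$n_classes == 1L) {
    rep(1L, length(y))
  } else {
    quality_classes(y, k_c = state$n_classes,
                    edges = state$class_edges)$classes
  }
  st <- update_node_stats(sel$state, sel$ids, cl)
  st <- refine_pruning(st)
  list(state = st, ids = sel$ids, y = y, paths = sel$paths,
       pruning_size = length(st$pruning), total_error = st$total_error,
       exhausted = sel$exhausted)
}
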