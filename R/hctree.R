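#' Euclidean distance between two points
#'
#' @param x1,x2 numeric vectors of equal length.
#' @return \eqn{\sqrt{\sum_i (x_{1i} - x_{2i})^2}}.
#' @export
euclidean_distance <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("dimension mismatch")
  sqrt(sum((x1 - x2)^2))
}

#' Ward similarity of two clusters (merged-cluster ESS)
#'
#' Error sum of squares of the union of two clusters about the merged
#' centroid: \eqn{ESS(c_1,c_2)=\sum_{x_i \in c_1\cup c_2} d(x_i, o)^2},
#' the quantity Ward linkage controls. The tree builder works with its
#' increase over the children's ESS, obtained incrementally via the
#' Lance-Williams recurrence.
#'
#' @param c1,c2 matrices of cluster member points (rows), disjoint and
#'   non-empty.
#' @return ESS of the merged cluster.
#' @export
ward_cost <- function(c1, c2) {
  c1 <- as.matrix(c1); c2 <- as.matrix(c2)
  if (nrow(c1) == 0L || nrow(c2) == 0L) stop("clusters must be non-empty")
  merged <- rbind(c1, c2)
  ctr <- colMeans(merged)
  sum(sweep(merged, 2L, ctr)^2)
}

#' Build the Ward-linkage merge tree of an unlabeled pool
#'
#' Deterministic greedy agglomeration: every step merges the active pair
#' whose merge minimally increases the total error sum of squares
#' (Lance-Williams update, O(n^2) memory). Exact cost ties break
#' lexicographically by the smallest sample id in each cluster. Merge
#' heights are the ESS increases and are non-decreasing (Ward linkage is
#' reducible); a violation beyond round-off is a build error.
#'
#' @param X matrix of pool samples (rows), n >= 2.
#' @param ids sample identifiers per row (default: row order).
#' @return an object of class \code{hctree} with nodes numbered
#'   1..n (leaves, in input row order) and n+1..2n-1 (merges, in merge
#'   order); fields: \code{merge} (hclust-style), \code{height} (ESS
#'   increase per merge), \code{children}, \code{parent},
#'   \code{n_leaves} per node, \code{leaf_sets} (leaf indices per node)
#'   and \code{leaf_ids}.
#' @export
build_hctree <- function(X, ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 points to build a tree")
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique")

  # Delta-ESS between singletons is d^2 / 2.
  D <- as.matrix(stats::dist(X))^2 / 2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1, n)
  minid <- ids                       # smallest sample id in each cluster
  node_of <- -seq_len(n)             # hclust convention: -leaf / +merge index

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    dmin <- min(D[active, active])
    cand <- which(D == dmin & outer(active, active, "&"), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      # order each pair so the smaller min-id cluster is on the left,
      # then take the lexicographically smallest (left, right) key
      key_l <- pmin(minid[cand[, 1L]], minid[cand[, 2L]])
      key_r <- pmax(minid[cand[, 1L]], minid[cand[, 2L]])
      cand <- cand[order(key_l, key_r)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]

    merge[s, ] <- c(node_of[i], node_of[j])
    height[s] <- dmin

    # Lance-Williams Ward update against every other active cluster
    keep <- which(active); keep <- keep[keep != i & keep != j]
    if (length(keep)) {
      si <- size[i]; sj <- size[j]; sk <- size[keep]
      Dnew <- ((si + sk) * D[i, keep] + (sj + sk) * D[j, keep] -
                 sk * dmin) / (si + sj + sk)
      D[i, keep] <- Dnew
      D[keep, i] <- Dnew
    }
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    size[i] <- size[i] + size[j]
    minid[i] <- min(minid[i], minid[j])
    node_of[i] <- s
  }

  if (any(diff(height) < -1e-8 * max(height, 1)))
    stop("build error: merge heights decreased (non-reducible sequence)")
  height <- cummax(height)  # iron out round-off wiggles only

  n_nodes <- 2L * n - 1L
  children <- matrix(NA_integer_, n_nodes, 2L)
  parent <- rep(NA_integer_, n_nodes)
  n_leaves <- c(rep(1L, n), integer(n - 1L))
  leaf_sets <- vector("list", n_nodes)
  for (v in seq_len(n)) leaf_sets[[v]] <- v
  for (s in seq_len(n - 1L)) {
    v <- n + s
    ch <- ifelse(merge[s, ] < 0L, -merge[s, ], n + merge[s, ])
    children[v, ] <- ch
    parent[ch] <- v
    n_leaves[v] <- n_leaves[ch[1L]] + n_leaves[ch[2L]]
    leaf_sets[[v]] <- c(leaf_sets[[ch[1L]]], leaf_sets[[ch[2L]]])
  }

  structure(list(n = n, merge = merge, height = height,
                 children = children, parent = parent,
                 n_leaves = n_leaves, leaf_sets = leaf_sets,
                 leaf_ids = ids, root = n_nodes),
            class = "hctree")
}

#' @export
print.hctree <- function(x, ...) {
  cat(sprintf("hctree: %d leaves, %d internal nodes, root ESS increase %.4g\n",
              x$n, x$n - 1L, x$height[x$n - 1L]))
  invisible(x)
}

#' Cut the merge tree into an initial pruning
#'
#' Undoes the \code{max_nodes - 1} highest merges, yielding an antichain
#' of \code{max_nodes} disjoint subtrees covering every leaf exactly
#' once; this is the working partition the active sampler refines. The
#' reference protocol uses 150 on a 392-leaf tree.
#'
#' @param tree an [build_hctree()] tree.
#' @param max_nodes pruning size, between 1 and the number of leaves.
#' @return integer vector of node numbers (the antichain).
#' @export
initial_pruning <- function(tree, max_nodes) {
  if (max_nodes < 1L || max_nodes > tree$n)
    stop("max_nodes must be in [1, ", tree$n, "]")
  pruning <- tree$root
  node_height <- function(v) if (v <= tree$n) -Inf else tree$height[v - tree$n]
  while (length(pruning) < max_nodes) {
    h <- vapply(pruning, node_height, numeric(1L))
    # split the highest merge; ties to the later merge (higher node number)
    cand <- which(h == max(h))
    pick <- cand[which.max(pruning[cand])]
    v <- pruning[pick]
    pruning <- c(pruning[-pick], tree$children[v, ])
  }
  sort(pruning)
}

#' Export a tree as nested JSON
#'
#' @param tree an [build_hctree()] tree.
#' @param path optional output file.
#' @return the JSON string, invisibly if written to a file.
#' @export
tree_to_json <- function(tree, path = NULL) {
  build <- function(v) {
    if (v <= tree$n) {
      list(node = v, leaf_id = tree$leaf_ids[v])
    } else {
      list(node = v, height = tree$height[v - tree$n],
           n_leaves = tree$n_leaves[v],
           children = lapply(tree$children[v, ], build))
    }
  }
  js <- jsonlite::toJSON(build(tree$root), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
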