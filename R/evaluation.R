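#' Root-mean-square error
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 1).
#' @return \eqn{\sqrt{\sum_i (y_i - \hat y_i)^2 / n}}.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty vectors")
  sqrt(mean((y_true - y_pred)^2))
}

#' Tracking precision
#'
#' \eqn{TP = 1 - \sigma^2_{error} / \sigma^2_{true}}: one minus the ratio
#' of the prediction-error variance to the true-output variance. A
#' constant bias leaves TP at 1; predicting the mean everywhere gives 0.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return TP value (<= 1).
#' @export
tracking_precision <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 points")
  v_true <- stats::var(y_true)
  if (v_true <= 0) stop("zero true variance")
  1 - stats::var(y_pred - y_true) / v_true
}

#' Benchmark protocol configuration
#'
#' Defaults follow the reference protocol: 800 simulated samples split
#' 400/400 train/test by alternating rows, 8 initially labeled training
#' samples (2%), learning step 20, pruning size 150, K = 3 phases,
#' all four variants, checkpoints after iterations 3 and 7, aggregated
#' over 10 seeds.
#'
#' @param n_train,n_test training/test sizes.
#' @param n_labeled_initial initially labeled training samples.
#' @param ns learning step (samples labeled per iteration).
#' @param n_iterations number of query iterations.
#' @param pruning_size initial tree-cut size for the active sampler.
#' @param K number of phases for ensemble learners, or \code{"auto"}.
#' @param variants subset of [variant_tags()].
#' @param seeds integer seeds, one protocol repeat each.
#' @param checkpoints iterations at which the summary table is reported.
#' @param gp_restarts GP optimizer restarts per fit.
#' @param rmse_target optional early-stop RMSE.
#' @param params simulator parameters ([kinetic_params()]).
#' @return a validated configuration list of class \code{protocol_config}.
#' @export
protocol_config <- function(n_train = 400L, n_test = 400L,
                            n_labeled_initial = 8L, ns = 20L,
                            n_iterations = 7L, pruning_size = 150L,
                            K = 3L, variants = variant_tags(),
                            seeds = 1:10, checkpoints = c(3L, 7L),
                            gp_restarts = 5L, rmse_target = NULL,
                            params = kinetic_params()) {
  stopifnot(ns >= 0, length(seeds) >= 1L, n_labeled_initial >= 1L,
            n_iterations >= 0L, all(variants %in% variant_tags()))
  structure(list(n_train = n_train, n_test = n_test,
                 n_labeled_initial = n_labeled_initial, ns = ns,
                 n_iterations = n_iterations, pruning_size = pruning_size,
                 K = K, variants = variants, seeds = seeds,
                 checkpoints = checkpoints, gp_restarts = gp_restarts,
                 rmse_target = rmse_target, params = params),
            class = "protocol_config")
}

# One protocol repeat: shared data, split and per-strategy labeled
# trajectories; learners are fitted per variant on the shared labeled
# sets so that sampling strategy is the only difference between
# same-learner variants.
run_protocol_seed <- function(cfg, seed) {
  data <- generate_dataset(cfg$params, cfg$n_train + cfg$n_test, seed = seed)
  train_idx <- seq(1L, 2L * cfg$n_train - 1L, by = 2L)
  test_idx <- setdiff(seq_len(cfg$n_train + cfg$n_test), train_idx)[seq_len(cfg$n_test)]
  train <- subset_ids(data, data$ids[train_idx])
  test <- subset_ids(data, data$ids[test_idx])

  sc <- fit_standardizer(train)          # all training inputs: labeled + pool
  Xtr <- apply_standardizer(sc, train$X)
  Xte <- apply_standardizer(sc, test$X)
  rownames(Xtr) <- NULL

  split <- split_initial(train, cfg$n_labeled_initial, seed = seed)
  oracle <- make_oracle(train)
  y0 <- oracle$query(split$labeled)

  strategies <- unique(vapply(cfg$variants, variant_strategy, character(1L)))
  labeled_by_iter <- list()              # [[strategy]][[iteration+1]] -> ids
  for (strat in strategies) {
    L <- split$labeled
    P <- split$pool
    hist <- list(L)
    if (strat == "active" && cfg$n_iterations > 0L) {
      pool_rows <- match(P, train$ids)
      tree <- build_hctree(Xtr[pool_rows, , drop = FALSE], ids = P)
      st <- init_sampler(tree, X_pool = Xtr[pool_rows, , drop = FALSE],
                         n_classes = 3L,
                         pruning_size = cfg$pruning_size, seed = seed)
      st <- refine_pruning(st)
    }
    for (it in seq_len(cfg$n_iterations)) {
      if (length(P) == 0L) { hist[[it + 1L]] <- L; next }
      if (strat == "random") {
        take <- with_seed(seed * 1000L + it,
                          sample(P, min(cfg$ns, length(P))))
        oracle$query(take)
      } else {
        res <- al_iteration(st, oracle, cfg$ns)
        st <- res$state
        take <- res$ids
      }
      L <- c(L, take)
      P <- setdiff(P, take)
      hist[[it + 1L]] <- L
    }
    labeled_by_iter[[strat]] <- hist
  }

  # the phase model sees all (observed) training inputs; fit once per
  # seed and reuse across ensemble refits
  phase_model <- if (any(vapply(cfg$variants, variant_learner,
                                character(1L)) == "ensemble")) {
    if (identical(cfg$K, "auto")) Xtr else {
      fit <- tryCatch(gmm_fit(Xtr, as.integer(cfg$K), seed = seed),
                      error = function(e) NULL)
      if (is.null(fit)) Xtr else fit$params
    }
  } else NULL

  rows <- list()
  for (tag in cfg$variants) {
    hist <- labeled_by_iter[[variant_strategy(tag)]]
    prev_n <- -1L
    model <- NULL
    for (it in 0:cfg$n_iterations) {
      L <- hist[[it + 1L]]
      res <- tryCatch({
        if (length(L) != prev_n) {       # refit only when the labeled set grew
          li <- sort(match(L, train$ids))  # order-free: same set, same fit
          model <- fit_learner(tag, Xtr[li, , drop = FALSE], train$y[li],
                               K = cfg$K, seed = seed,
                               restarts = cfg$gp_restarts,
                               X_phases = phase_model)
          prev_n <- length(L)
        }
        pr <- predict(model, Xte)
        data.frame(variant = tag, seed = seed, iteration = it,
                   n_labeled = length(L),
                   rmse = rmse(test$y, pr$mean),
                   tp = tracking_precision(test$y, pr$mean),
                   failed = FALSE, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("variant %s, seed %d, iteration %d failed: %s",
                        tag, seed, it, conditionMessage(e)))
        data.frame(variant = tag, seed = seed, iteration = it,
                   n_labeled = length(L), rmse = NA_real_, tp = NA_real_,
                   failed = TRUE, stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
      if (!is.null(cfg$rmse_target) && !is.na(res$rmse) &&
          res$rmse <= cfg$rmse_target) break
    }
  }
  list(results = do.call(rbind, rows), query_count = oracle$count())
}

#' Run the benchmark protocol
#'
#' For every seed: simulate a dataset, split train/test, draw the
#' initial labeled set, run every requested variant through the query
#' iterations (the learner is refitted from scratch after each), and
#' score RMSE and tracking precision on the fixed test set at every
#' iteration. Per-cell failures are recorded without aborting the rest.
#'
#' @param cfg a [protocol_config()].
#' @return an object of class \code{iteration_report}: \code{results}
#'   (variant, seed, iteration, n_labeled, rmse, tp),
#'   \code{summary} (per variant x iteration means/sds over seeds),
#'   \code{checkpoints} (reference-style table at the configured
#'   checkpoints) and the \code{config}.
#' @export
run_protocol <- function(cfg = protocol_config()) {
  runs <- lapply(cfg$seeds, function(s) run_protocol_seed(cfg, s))
  results <- do.call(rbind, lapply(runs, `[[`, "results"))
  summary <- stats::aggregate(cbind(rmse, tp) ~ variant + iteration,
                              data = results, FUN = mean, na.action = stats::na.omit)
  sds <- stats::aggregate(cbind(rmse, tp) ~ variant + iteration,
                          data = results, FUN = stats::sd, na.action = stats::na.omit)
  names(sds)[3:4] <- c("rmse_sd", "tp_sd")
  summary <- merge(summary, sds, by = c("variant", "iteration"))
  summary <- summary[order(summary$iteration, summary$variant), ]
  checkpoints <- summary[summary$iteration %in% cfg$checkpoints, ]
  structure(list(results = results, summary = summary,
                 checkpoints = checkpoints,
                 query_counts = vapply(runs, `[[`, numeric(1L), "query_count"),
                 config = cfg),
            class = "iteration_report")
}

#' @export
print.iteration_report <- function(x, ...) {
  cat("Benchmark checkpoints (means over seeds):\n")
  print(x$checkpoints, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sweep the pruning size of the active sampler
#'
#' Reruns the active-learning variants of the protocol at several
#' pruning sizes with identical seeds, so curve differences are
#' attributable to pruning granularity only.
#'
#' @param cfg a [protocol_config()].
#' @param sizes pruning sizes to evaluate.
#' @return data frame of per-size results (column \code{pruning_size}
#'   added).
#' @export
pruning_sweep <- function(cfg, sizes) {
  al_variants <- intersect(cfg$variants, c("AL-GPR", "AL-EGPR"))
  if (!length(al_variants)) stop("no active-learning variants in config")
  out <- lapply(sizes, function(sz) {
    cfg_sz <- cfg
    cfg_sz$pruning_size <- sz
    cfg_sz$variants <- al_variants
    rep <- run_protocol(cfg_sz)
    cbind(pruning_size = sz, rep$results)
  })
  do.call(rbind, out)
}

#' Write an iteration report to JSON and tidy CSV
#'
#' @param report an [run_protocol()] report.
#' @param json_path,csv_path output files (either may be NULL).
#' @return invisible NULL.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    doc <- list(summary = report$summary, checkpoints = report$checkpoints,
                results = report$results,
                query_counts = report$query_counts)
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), json_path)
  }
  if (!is.null(csv_path))
    utils::write.csv(report$results, csv_path, row.names = FALSE)
  invisible(NULL)
}
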