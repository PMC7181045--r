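#' Column schema of a process-data CSV
#'
#' The on-disk layout is a plain CSV with header \code{id,u1..u7[,y]}:
#' a stable integer sample identifier, the seven measured process inputs
#' (culture volume, agitator power, pH, substrate feed temperature,
#' fermenter temperature, substrate feed rate, aeration rate), and an
#' optional quality column (penicillin concentration, g/L) that is empty
#' for unlabeled rows.
#'
#' @param inputs character vector of input column names.
#' @param id name of the identifier column.
#' @param quality name of the optional quality column.
#' @return a schema list used by [load_dataset()].
#' @export
process_schema <- function(inputs = paste0("u", 1:7), id = "id", quality = "y") {
  list(id = id, inputs = inputs, quality = quality)
}

#' Construct a process dataset
#'
#' Container shared by every other module: an input matrix, an optional
#' quality vector with \code{NA} marking unlabeled samples, and stable
#' integer sample identifiers. All cross-module references use ids,
#' never row positions.
#'
#' @param X numeric matrix (samples x input variables).
#' @param y optional numeric quality vector; \code{NA} = unlabeled.
#' @param ids optional integer identifiers (default: row order).
#' @return an object of class \code{process_dataset} with fields
#'   \code{ids}, \code{X}, \code{y} and logical \code{mask}
#'   (\code{TRUE} = labeled).
#' @export
process_dataset <- function(X, y = NULL, ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("u", seq_len(ncol(X)))
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (length(ids) != n) stop("ids must have one entry per row of X")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != n) stop("y must have one entry per row of X")
    if (any(is.infinite(y) | is.nan(y))) stop("labeled y values must be finite")
  }
  mask <- if (is.null(y)) rep(FALSE, n) else !is.na(y)
  structure(list(ids = ids, X = X, y = y, mask = mask),
            class = "process_dataset")
}

#' @export
print.process_dataset <- function(x, ...) {
  cat(sprintf("process_dataset: %d samples x %d inputs, %d labeled\n",
              nrow(x$X), ncol(x$X), sum(x$mask)))
  invisible(x)
}

#' @export
dim.process_dataset <- function(x) dim(x$X)

#' Subset a dataset by sample ids
#'
#' @param data a [process_dataset()].
#' @param ids sample identifiers to keep (order preserved).
#' @param drop_y drop the quality column from the result.
#' @return a \code{process_dataset} with the requested rows.
#' @export
subset_ids <- function(data, ids, drop_y = FALSE) {
  idx <- match(ids, data$ids)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  y <- if (drop_y || is.null(data$y)) NULL else data$y[idx]
  process_dataset(data$X[idx, , drop = FALSE], y = y, ids = data$ids[idx])
}

#' Load a process dataset from CSV
#'
#' @param path CSV file with a header row; missing quality = empty field.
#' @param schema column-name map from [process_schema()].
#' @return a [process_dataset()]; the labeled mask is set from the presence
#'   of quality values and row order is preserved.
#' @export
load_dataset <- function(path, schema = process_schema()) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(c(schema$id, schema$inputs), names(df))
  if (length(missing_cols))
    stop("schema error: column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  for (cl in schema$inputs) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                     cl, bad[1L]))
      df[[cl]] <- vn
    }
  }
  X <- as.matrix(df[schema$inputs])
  y <- if (schema$quality %in% names(df)) {
    v <- df[[schema$quality]]
    if (is.character(v)) v[v == ""] <- NA
    as.numeric(v)
  } else NULL
  process_dataset(X, y = y, ids = df[[schema$id]])
}

#' Write a process dataset to CSV
#'
#' @param data a [process_dataset()].
#' @param path output file.
#' @param schema column-name map.
#' @return \code{path}, invisibly.
#' @export
save_dataset <- function(data, path, schema = process_schema()) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))  # lossless
  df <- data.frame(data$ids, apply(data$X, 2L, fmt), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(schema$id, schema$inputs)
  if (!is.null(data$y)) df[[schema$quality]] <- fmt(data$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Fit a column standardizer
#'
#' Column means and (sample) standard deviations over a row subset,
#' used to z-score inputs. Constant columns are rejected: a zero scale
#' would make standardization degenerate.
#'
#' @param data a [process_dataset()] or numeric matrix.
#' @param rows optional row index/logical selector (default: all rows).
#' @return an object of class \code{scaler} with \code{center} and
#'   \code{scale} per column.
#' @export
fit_standardizer <- function(data, rows = NULL) {
  X <- if (inherits(data, "process_dataset")) data$X else as.matrix(data)
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a standardizer")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  degenerate <- !is.finite(scale) | scale <= 0
  if (any(degenerate))
    stop("degenerate scale: constant column(s) ",
         paste(colnames(X)[degenerate], collapse = ", "))
  structure(list(center = center, scale = scale), class = "scaler")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param scaler a [fit_standardizer()] result.
#' @param data a [process_dataset()] or numeric matrix.
#' @param invert map standardized values back to the original scale.
#' @return object of the same type as \code{data} with transformed inputs;
#'   the original is untouched.
#' @export
apply_standardizer <- function(scaler, data, invert = FALSE) {
  is_ds <- inherits(data, "process_dataset")
  X <- if (is_ds) data$X else as.matrix(data)
  if (ncol(X) != length(scaler$center))
    stop("dimension mismatch: scaler has ", length(scaler$center),
         " columns, data has ", ncol(X))
  Z <- if (invert) {
    sweep(sweep(X, 2L, scaler$scale, "*"), 2L, scaler$center, "+")
  } else {
    sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
  }
  if (is_ds) process_dataset(Z, y = data$y, ids = data$ids) else Z
}

#' Initial labeled/unlabeled split
#'
#' Selects the starting labeled set of the active-learning loop; the
#' remaining rows form the unlabeled pool (inputs only). The reference
#' protocol labels 2% of 400 training samples (8 rows), leaving a
#' 392-sample pool.
#'
#' @param data a [process_dataset()] whose rows all carry ground-truth y.
#' @param n_labeled_initial number of initially labeled samples.
#' @param seed integer seed making the selection reproducible.
#' @param selection \code{"random"} (uniform without replacement) or
#'   \code{"stratified"} (one draw per contiguous block of row order,
#'   for reproducibility studies on time-indexed data).
#' @return list with integer id vectors \code{labeled} and \code{pool}
#'   (a disjoint cover of the rows).
#' @export
split_initial <- function(data, n_labeled_initial, seed = 1L,
                          selection = c("random", "stratified")) {
  selection <- match.arg(selection)
  n <- nrow(data$X)
  if (n_labeled_initial < 1L || n_labeled_initial > n)
    stop("n_labeled_initial must be in [1, ", n, "]")
  idx <- with_seed(seed, {
    if (selection == "random") {
      sort(sample.int(n, n_labeled_initial))
    } else {
      breaks <- floor(seq(0L, n, length.out = n_labeled_initial + 1L))
      vapply(seq_len(n_labeled_initial), function(b) {
        lo <- breaks[b] + 1L; hi <- breaks[b + 1L]
        if (lo > hi) lo else sample(seq(lo, hi), 1L)
      }, integer(1L))
    }
  })
  list(labeled = data$ids[idx], pool = data$ids[-idx])
}
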