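#' Random forest regression
#'
#' Thin, seed-deterministic wrapper around the classical bagged-CART
#' ensemble (bootstrap rows, random feature subsets per split, mean
#' aggregation of tree predictions) as implemented in the randomForest
#' package. `min_leaf` is the minimum number of observations in a terminal
#' node.
#'
#' @param X matrix or [spectra_set]
#' @param y aligned numeric response or [reference_table]
#' @param n_trees number of trees (default 100)
#' @param min_leaf minimum terminal-node size (default 5)
#' @param seed integer seed; fits are deterministic given it
#' @return object of class `rfr_model`
#' @export
fit_rfr <- function(X, y, n_trees = 100L, min_leaf = 5L, seed = 1L) {
  if (inherits(X, "spectra_set")) {
    y <- align_refs(X, y)
    X <- X$matrix
  } else y <- as.numeric(y)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (min_leaf < 1) stop("min_leaf must be >= 1")
  if (min_leaf > nrow(X)) stop("min_leaf exceeds the number of samples")
  fit <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = X, y = y, ntree = as.integer(n_trees),
                               nodesize = as.integer(min_leaf)))
  structure(list(forest = fit, n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "rfr_model")
}

#' @export
print.rfr_model <- function(x, ...) {
  cat(sprintf("rfr_model: %d trees, min leaf %d\n", x$n_trees, x$min_leaf))
  invisible(x)
}

#' @export
predict.rfr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$matrix
  as.numeric(predict(object$forest, newdata))
}

#' Tune random forest hyperparameters by cross-validation
#'
#' Grid search over tree counts and terminal-node sizes, scored by pooled
#' k-fold RMSE; ties break toward fewer trees, then the larger leaf
#' (smaller model first).
#'
#' @param X matrix or [spectra_set]; `y` aligned response
#' @param y numeric response or [reference_table]
#' @param trees_grid candidate tree counts (default 100, 200, ..., 1000)
#' @param leaf_grid candidate minimum leaf sizes (default 1..10)
#' @param folds CV folds (default 5)
#' @param seed integer seed (folds and forests)
#' @return list with `n_trees`, `min_leaf`, `cv_rmse` (matrix over the
#'   grid)
#' @export
tune_rfr <- function(X, y, trees_grid = seq(100L, 1000L, by = 100L),
                     leaf_grid = 1:10, folds = 5L, seed = 1L) {
  if (inherits(X, "spectra_set")) {
    y <- align_refs(X, y)
    X <- X$matrix
  } else y <- as.numeric(y)
  if (!length(trees_grid) || !length(leaf_grid))
    stop("grids must be nonempty")
  if (length(trees_grid) == 1L && length(leaf_grid) == 1L)
    return(list(n_trees = as.integer(trees_grid),
                min_leaf = as.integer(leaf_grid), cv_rmse = NULL))
  n <- nrow(X)
  fold_id <- cv_folds(n, min(folds, n), seed)
  rmse <- matrix(NA_real_, length(trees_grid), length(leaf_grid),
                 dimnames = list(trees_grid, leaf_grid))
  for (ti in seq_along(trees_grid)) for (li in seq_along(leaf_grid)) {
    sse <- 0
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      fit <- fit_rfr(X[tr, , drop = FALSE], y[tr],
                     n_trees = trees_grid[ti], min_leaf = leaf_grid[li],
                     seed = seed + f)
      sse <- sse + sum((y[!tr] - predict(fit, X[!tr, , drop = FALSE]))^2)
    }
    rmse[ti, li] <- sqrt(sse / n)
  }
  # ties: fewer trees, then larger leaf
  best <- Inf; bt <- NA_integer_; bl <- NA_integer_
  for (ti in seq_along(trees_grid)) for (li in rev(seq_along(leaf_grid))) {
    if (rmse[ti, li] < best - 1e-15) {
      best <- rmse[ti, li]; bt <- ti; bl <- li
    }
  }
  list(n_trees = as.integer(trees_grid[bt]),
       min_leaf = as.integer(leaf_grid[bl]), cv_rmse = rmse)
}
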