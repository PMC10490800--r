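#' Successive projections algorithm: one chain
#'
#' Starting from column `k0`, iteratively replaces every remaining column
#' by its component orthogonal to the most recently selected column and
#' selects the column with the largest projected norm. The resulting chain
#' has minimal collinearity among its members.
#'
#' @param X numeric matrix (samples x wavelengths); callers normally pass
#'   mean-centered columns
#' @param k0 index of the start column
#' @param N chain length, `N <= min(samples, columns)` (for mean-centered
#'   input one dimension is lost, so [spa_select()] caps its sizes at
#'   `samples - 1`)
#' @return integer vector `c(k0, k1, ..., k_{N-1})`; the chain is
#'   truncated with a warning if every remaining projected norm falls
#'   below 1e-12 (rank exhausted)
#' @export
spa_chain <- function(X, k0, N) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k0 < 1 || k0 > p) stop("k0 out of range")
  if (N < 1 || N > min(n, p))
    stop("N must lie in [1, min(samples, columns)]")
  P <- X
  chain <- integer(N)
  chain[1] <- as.integer(k0)
  remaining <- setdiff(seq_len(p), k0)
  for (step in seq_len(N - 1L)) {
    last <- P[, chain[step]]
    denom <- sum(last^2)
    if (denom < 1e-24) {
      warning("chain truncated: projections numerically rank-exhausted")
      return(chain[seq_len(step)])
    }
    proj_coef <- as.numeric(crossprod(last, P[, remaining, drop = FALSE])) /
      denom
    P[, remaining] <- P[, remaining, drop = FALSE] -
      outer(last, proj_coef)
    norms2 <- colSums(P[, remaining, drop = FALSE]^2)
    if (max(norms2) < 1e-24) {
      warning("chain truncated: projections numerically rank-exhausted")
      return(chain[seq_len(step)])
    }
    nxt <- remaining[which.max(norms2)]
    chain[step + 1L] <- nxt
    remaining <- setdiff(remaining, nxt)
  }
  chain
}

#' Successive projections algorithm: subset selection
#'
#' For every candidate start column and every subset size `N` in
#' `[Nmin, Nmax]`, builds the projection chain (one chain per start; the
#' size-`N` subset is its prefix) and scores the subset by pooled k-fold
#' PLS RMSECV. Returns the subset with minimal RMSECV; ties break toward
#' the smaller size, then the smaller start index.
#'
#' @param X a [spectra_set] or matrix; columns are mean-centered
#'   internally before the projections
#' @param y aligned [reference_table] or numeric response
#' @param Nmin,Nmax smallest/largest subset size tried
#' @param cv_folds folds for scoring (default 10)
#' @param pls_components fixed component count; `NULL` selects once by
#'   10-fold CV on the full-band data (cap `max_nc`)
#' @param max_nc cap for the automatic component choice (default 10)
#' @param starts candidate start columns (default: all columns)
#' @param seed integer seed (fold assignment)
#' @return list of class `selection_result`: `selected_indices` (sorted),
#'   `selected_wavelengths`, `rmsecv_trace` (best RMSECV per size,
#'   minimized over starts), `chosen_size`, `chosen_start`,
#'   `pls_components`
#' @export
spa_select <- function(X, y, Nmin = 1L, Nmax = 30L, cv_folds = 10L,
                       pls_components = NULL, max_nc = 10L,
                       starts = NULL, seed = 1L) {
  wl <- if (inherits(X, "spectra_set")) X$wavelengths else NULL
  if (inherits(X, "spectra_set")) {
    y <- align_refs(X, y)
    X <- X$matrix
  } else y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (Nmax < Nmin) stop("Nmax must be >= Nmin")
  if (Nmin < 1) stop("Nmin must be >= 1")
  Nmax <- min(Nmax, n - 1L, p)
  if (Nmax < Nmin) stop("Nmax after rank capping is below Nmin")
  if (is.null(starts)) starts <- seq_len(p)
  Xc <- sweep(X, 2, colMeans(X))
  fold_id <- cv_folds(n, min(cv_folds, n), as.integer(seed) %% 100000L + 1L)
  if (is.null(pls_components))
    pls_components <- select_nc(X, y, max_nc = max_nc, folds = 10L,
                                seed = seed)$nc

  best <- list(rmse = Inf, size = NA_integer_, start = NA_integer_,
               subset = NULL)
  size_trace <- rep(Inf, Nmax - Nmin + 1L)
  for (s in starts) {
    chain <- suppressWarnings(spa_chain(Xc, s, Nmax))
    if (length(chain) < Nmin) next
    for (N in seq(Nmin, min(Nmax, length(chain)))) {
      subset <- chain[seq_len(N)]
      nc_cv <- min(pls_components, N)
      r <- pls_cv_rmse(X[, subset, drop = FALSE], y, nc_cv,
                       folds = cv_folds, fold_id = fold_id)
      j <- N - Nmin + 1L
      if (r < size_trace[j]) size_trace[j] <- r
      if (r < best$rmse - 1e-15 ||
          (abs(r - best$rmse) <= 1e-15 &&
           (N < best$size || (N == best$size && s < best$start)))) {
        best <- list(rmse = r, size = N, start = s, subset = subset)
      }
    }
  }
  sel <- sort(unique(best$subset))
  structure(list(method = "SPA",
                 selected_indices = sel,
                 selected_wavelengths = if (!is.null(wl)) wl[sel] else NULL,
                 rmsecv_trace = size_trace,
                 sizes = seq(Nmin, Nmax),
                 chosen_size = best$size,
                 chosen_start = best$start,
                 rmsecv = best$rmse,
                 pls_components = pls_components,
                 seed = as.integer(seed)),
            class = "selection_result")
}
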