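#' Normalized PLS coefficient weights
#'
#' The importance weight of wavelength i is its absolute PLS regression
#' coefficient normalized over the variables in the model:
#' `w_i = |B_i| / sum_j |B_j|`. Larger weight, more important variable.
#'
#' @param B numeric vector of PLS regression coefficients (per variable)
#' @return numeric weight vector, nonnegative, summing to 1
#' @export
coefficient_weights <- function(B) {
  B <- abs(as.numeric(B))
  s <- sum(B)
  if (s == 0) stop("all regression coefficients are zero")
  B / s
}

#' Exponentially decreasing retention schedule (EDF)
#'
#' Fraction of wavelengths retained at sampling run i of N:
#' `r_i = mu * exp(-k i)` with `mu = (n/2)^(1/(N-1))` and
#' `k = ln(n/2) / (N-1)`, equivalently `r_i = (n/2)^((1-i)/(N-1))`.
#' All variables are retained at run 1 (`r_1 = 1`) and exactly two survive
#' at run N (`r_N = 2/n`); the schedule drops fast at first and slowly at
#' the end (coarse then fine selection).
#'
#' @param i run index (vectorized), `1 <= i <= N`
#' @param n total number of wavelengths (> 2)
#' @param N total number of sampling runs (>= 2)
#' @return retention ratio(s) in `(0, 1]`
#' @export
edf_ratio <- function(i, n, N) {
  if (n <= 2) stop("n must be > 2")
  if (N < 2) stop("N must be >= 2")
  if (any(i < 1 | i > N)) stop("run index i must lie in [1, N]")
  mu <- (n / 2)^(1 / (N - 1))
  k <- log(n / 2) / (N - 1)
  mu * exp(-k * i)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative characteristic-wavelength selection. At each of `n_runs`
#' Monte Carlo runs a random sample subset (default 80 percent) fits a PLS
#' model on the currently retained wavelengths; the normalized absolute
#' coefficients [coefficient_weights()] rank the variables; the enforced
#' EDF step keeps the top `ceiling(r_i * n)` of them; optionally an
#' adaptive reweighted sampling step draws the same number of variables
#' with replacement, with probability proportional to weight, and keeps
#' the unique draws. Each run's retained set is scored by k-fold pooled
#' RMSECV on the full data; the run with minimal RMSECV (ties toward the
#' earlier run) yields the selected wavelengths.
#'
#' @param X a [spectra_set] (typically after preprocessing, e.g. SD) or
#'   matrix
#' @param y aligned [reference_table] or numeric response
#' @param n_runs number of Monte Carlo sampling runs N (default 40)
#' @param mc_sample_fraction fraction of samples drawn per run (default
#'   0.80)
#' @param cv_folds folds for the per-run RMSECV (default 10)
#' @param pls_components fixed component count; `NULL` selects once by
#'   10-fold CV on the full-band data (cap `max_nc`)
#' @param max_nc cap for the automatic component choice (default 10)
#' @param use_ars additionally apply the adaptive reweighted sampling draw
#'   after the enforced EDF cut (default `FALSE`: retention follows the EDF
#'   counts exactly, the regime in which a run-17-of-40 selection on a
#'   244-band grid keeps 34 wavelengths; with ARS the unique-draw attrition
#'   shrinks retention well below the EDF schedule)
#' @param seed integer seed; the whole selection is deterministic given it
#' @return list of class `selection_result`: `method`, `selected_indices`
#'   (sorted, into the input grid), `selected_wavelengths` (nm),
#'   `rmsecv_trace` (length `n_runs`), `n_retained_trace`, `chosen_run`,
#'   `pls_components`
#' @export
cars_select <- function(X, y, n_runs = 40L, mc_sample_fraction = 0.80,
                        cv_folds = 10L, pls_components = NULL,
                        max_nc = 10L, use_ars = FALSE, seed = 1L) {
  wl <- if (inherits(X, "spectra_set")) X$wavelengths else NULL
  if (inherits(X, "spectra_set")) {
    y <- align_refs(X, y)
    X <- X$matrix
  } else y <- as.numeric(y)
  n_samp <- nrow(X); nvar <- ncol(X)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (mc_sample_fraction <= 0 || mc_sample_fraction >= 1)
    stop("mc_sample_fraction must lie in (0, 1)")
  if (n_samp < 2 * cv_folds) stop("need at least 2 x cv_folds samples")
  if (is.null(pls_components))
    pls_components <- select_nc(X, y, max_nc = max_nc, folds = 10L,
                                seed = seed)$nc

  retained <- seq_len(nvar)
  trace_rmse <- numeric(n_runs)
  trace_nvar <- integer(n_runs)
  sets <- vector("list", n_runs)
  n_sub <- max(2L, round(mc_sample_fraction * n_samp))
  # every run is scored on the same deterministic folds
  fold_id <- cv_folds(n_samp, cv_folds, as.integer(seed) %% 100000L + 1L)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_runs)) {
      sub <- sample.int(n_samp, n_sub)
      nc_i <- min(pls_components, length(retained), n_sub - 1L)
      if (length(retained) < pls_components)
        warning(sprintf(
          "run %d: retained variables (%d) below pls_components (%d); using %d",
          i, length(retained), pls_components, nc_i))
      fit <- simpls(X[sub, retained, drop = FALSE], y[sub], nc_i,
                    partial = TRUE)
      w <- coefficient_weights(fit$coefficients$b)
      keep_n <- min(ceiling(edf_ratio(i, nvar, n_runs) * nvar),
                    length(retained))
      ord <- order(w, decreasing = TRUE)
      retained <- retained[ord[seq_len(keep_n)]]
      w <- w[ord[seq_len(keep_n)]]
      if (use_ars && length(retained) > 1 && sum(w) > 0) {
        draws <- sample(length(retained), size = keep_n, replace = TRUE,
                        prob = w)
        retained <- retained[unique(draws)]
      }
      retained <- sort(retained)
      # score the retained set at its own best component count (<= the cap),
      # so small and large subsets are compared fairly
      nc_cv <- seq_len(min(pls_components, length(retained)))
      trace_rmse[i] <- min(pls_cv_rmse(X[, retained, drop = FALSE], y, nc_cv,
                                       folds = cv_folds, fold_id = fold_id))
      trace_nvar[i] <- length(retained)
      sets[[i]] <- retained
    }
  })
  chosen <- which.min(trace_rmse)
  sel <- sets[[chosen]]
  structure(list(method = "CARS",
                 selected_indices = sel,
                 selected_wavelengths = if (!is.null(wl)) wl[sel] else NULL,
                 rmsecv_trace = trace_rmse,
                 n_retained_trace = trace_nvar,
                 chosen_run = chosen,
                 pls_components = pls_components,
                 seed = as.integer(seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d wavelengths", x$method,
              length(x$selected_indices)))
  if (!is.null(x$chosen_run))
    cat(sprintf(", chosen run %d, RMSECV %.4f", x$chosen_run,
                x$rmsecv_trace[x$chosen_run]))
  if (!is.null(x$chosen_size))
    cat(sprintf(", chosen size %d, RMSECV %.4f", x$chosen_size,
                min(x$rmsecv_trace)))
  cat("\n")
  invisible(x)
}
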