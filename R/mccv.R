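#' Monte Carlo cross-validation outlier detection
#'
#' Repeatedly (default 1000 times) draws a random calibration subset
#' (default 75 percent of samples), fits a PLS model on it, and predicts
#' the held-out samples. Each sample accumulates a set of prediction
#' residuals `y - yhat` over the iterations in which it was held out; the
#' per-sample mean (MEAN) and standard deviation (STD) of those residuals
#' expose abnormal samples, which sit away from the main cloud in the
#' MEAN-STD plane.
#'
#' The PLS component count is chosen once by k-fold cross-validation on the
#' full data (capped at `max_nc`) and held fixed across iterations.
#' Outlier screening runs on the trimmed raw spectra, before preprocessing.
#'
#' @param X a [spectra_set] (or matrix)
#' @param y a [reference_table] aligned by sample_id (or numeric vector)
#' @param train_fraction fraction used as calibration set each iteration
#'   (default 0.75)
#' @param n_iterations number of Monte Carlo draws (default 1000, >= 100)
#' @param pls_components fixed component count; `NULL` (default) selects it
#'   by 10-fold CV capped at `max_nc`
#' @param max_nc cap for the automatic component choice (default 15)
#' @param seed integer seed; output is deterministic given the seed
#' @return data.frame of class `outlier_report`: `sample_id`, `mean`,
#'   `std`, `n_appearances`, plus attributes `pls_components` and `seed`
#' @export
mccv_residuals <- function(X, y, train_fraction = 0.75,
                           n_iterations = 1000L, pls_components = NULL,
                           max_nc = 15L, seed = 1L) {
  ids <- if (inherits(X, "spectra_set")) X$sample_ids else
    sprintf("S%03d", seq_len(nrow(X)))
  if (inherits(X, "spectra_set")) {
    y <- align_refs(X, y)
    X <- X$matrix
  } else y <- as.numeric(y)
  n <- nrow(X)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (n_iterations < 100) stop("n_iterations must be >= 100")
  n_train <- round(train_fraction * n)
  if (n_train < 2 || n_train >= n)
    stop("not enough samples for a nonempty calibration and held-out set")
  if (is.null(pls_components)) {
    # the data screened here may contain the very outliers being hunted,
    # and gross outliers drag the CV-optimal component count toward
    # underfitting; break the circularity with a provisional screen:
    # (1) choose a provisional count by an outlier-robust CV loss (median
    # absolute held-out residual), (2) set aside rows whose held-out
    # residual is unambiguously deviant (robust z > 6) at that count,
    # (3) choose the final count by plain RMSECV on the screened rows
    ncs <- seq_len(max(1L, min(max_nc, n - 1L, ncol(X))))
    res <- pls_cv_residuals(X, y, ncs, folds = 10L, seed = seed)
    nc0 <- which.min(apply(abs(res), 2, stats::median))
    r0 <- res[, nc0]
    sc <- stats::mad(r0)
    keep0 <- if (sc > 0) abs(r0 - stats::median(r0)) / sc <= 6
             else rep(TRUE, n)
    pls_components <- select_nc(X[keep0, , drop = FALSE], y[keep0],
                                max_nc = max_nc, folds = 10L,
                                seed = seed)$nc
  }
  if (pls_components >= n_train)
    stop("pls_components must be smaller than the calibration subset size")

  rsum <- numeric(n); rsumsq <- numeric(n); cnt <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(n_iterations)) {
      tr <- sample.int(n, n_train)
      fit <- simpls(X[tr, , drop = FALSE], y[tr],
                    min(pls_components, n_train - 1L), partial = TRUE)
      te <- setdiff(seq_len(n), tr)
      res <- y[te] - (fit$coefficients$b0 +
                        X[te, , drop = FALSE] %*% fit$coefficients$b)
      rsum[te] <- rsum[te] + res
      rsumsq[te] <- rsumsq[te] + res^2
      cnt[te] <- cnt[te] + 1L
    }
  })
  if (any(cnt == 0))
    warning(sprintf("insufficient coverage: %d sample(s) never held out",
                    sum(cnt == 0)))
  mu <- rsum / cnt
  std <- sqrt(pmax(0, (rsumsq - cnt * mu^2) / pmax(1, cnt - 1L)))
  out <- data.frame(sample_id = ids, mean = mu, std = std,
                    n_appearances = cnt, stringsAsFactors = FALSE)
  attr(out, "pls_components") <- pls_components
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' Flag abnormal samples from an MCCV report
#'
#' Default rule: a sample is abnormal when its robust z-score exceeds
#' `z_threshold` on the MEAN axis (two-sided) or the STD axis (one-sided
#' high: an abnormally small residual spread is not suspicious). The robust
#' score uses the double MAD -- the median absolute deviation computed
#' separately above and below the median -- so the inherently right-skewed
#' STD axis is scaled by its own upper tail rather than by a symmetric
#' spread estimate. When the MAD of an axis is zero the rule falls back to
#' the classical mean/sd z-score with a warning.
#'
#' @param report an `outlier_report` from [mccv_residuals()]
#' @param z_threshold flag threshold on the robust z-score (default 3)
#' @param robust use median/double-MAD scores (default `TRUE`); `FALSE`
#'   uses classical mean/sd
#' @return character vector of flagged sample IDs, sorted by decreasing
#'   deviation
#' @export
flag_outliers <- function(report, z_threshold = 3, robust = TRUE) {
  stopifnot(inherits(report, "outlier_report") || is.data.frame(report))
  zscore <- function(x) {
    if (robust) {
      med <- stats::median(x)
      dev <- x - med
      up <- stats::median(abs(dev[dev >= 0])) * 1.4826
      lo <- stats::median(abs(dev[dev <= 0])) * 1.4826
      if (up == 0 || lo == 0) {
        if (stats::mad(x) > 0) {
          sc <- stats::mad(x)
          return((x - med) / sc)
        }
        warning("MAD is zero on one axis; falling back to classical z-score")
        if (stats::sd(x) == 0) return(rep(0, length(x)))
        return((x - mean(x)) / stats::sd(x))
      }
      return(ifelse(dev >= 0, dev / up, dev / lo))
    }
    if (stats::sd(x) == 0) return(rep(0, length(x)))
    (x - mean(x)) / stats::sd(x)
  }
  zm <- abs(zscore(report$mean))
  zs <- pmax(0, zscore(report$std))
  dev <- pmax(zm, zs)
  flagged <- which(zm > z_threshold | zs > z_threshold)
  report$sample_id[flagged[order(dev[flagged], decreasing = TRUE)]]
}
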