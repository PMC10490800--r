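#' Moisture content from drying masses
#'
#' Oven-drying reference method: `H = 100 (M1 - M2) / M1`, the mass
#' fraction of water lost on drying, in percent.
#'
#' @param m1 mass before drying (g), > 0
#' @param m2 mass after drying (g), `0 <= m2 <= m1`
#' @return moisture content in percent; vectorized
#' @export
#' @examples
#' moisture_from_mass(140, 126)  # 10
moisture_from_mass <- function(m1, m2) {
  if (any(m1 <= 0)) stop("mass before drying must be > 0")
  if (any(m2 < 0)) stop("mass after drying must be >= 0")
  if (any(m2 > m1)) stop("mass gain during drying is impossible (m2 > m1)")
  100 * (m1 - m2) / m1
}

#' Chemometric evaluation metrics
#'
#' Computes the standard calibration/validation metrics: the coefficient of
#' determination `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `RMSE = sqrt(mean((y - yhat)^2))`; for the test role additionally
#' `RPD = sd(y) / RMSEP` (n-1 sd of the reference values) and the
#' bias-corrected standard error of prediction
#' `SE = sqrt(sum((e - mean(e))^2) / (n - 1))` with `e = y - yhat`.
#'
#' @param y reference values (percent moisture)
#' @param yhat predictions
#' @param role one of `"training"`, `"cv"`, `"test"`; RPD and SE are
#'   reported only for `"test"`
#' @return list with `r2`, `rmse`, and for the test role `rpd` and `se`
#' @export
evaluate <- function(y, yhat, role = c("training", "cv", "test")) {
  role <- match.arg(role)
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  n <- length(y)
  if (n < 2 || length(yhat) != n)
    stop("y and yhat must have equal length >= 2")
  ss_tot <- sum((y - mean(y))^2)
  e <- y - yhat
  rmse <- sqrt(mean(e^2))
  r2 <- if (ss_tot <= 0) {
    warning("zero variance in reference values: R2 undefined")
    NA_real_
  } else 1 - sum(e^2) / ss_tot
  out <- list(r2 = r2, rmse = rmse, role = role)
  if (role == "test") {
    out$rpd <- if (rmse > 0 && ss_tot > 0) stats::sd(y) / rmse else NA_real_
    out$se <- sqrt(sum((e - mean(e))^2) / (n - 1))
  }
  out
}

#' Standard error of the laboratory from duplicate measurements
#'
#' For duplicate reference determinations, `SEL = sqrt(sum(d_i^2) / (2 m))`
#' over the `m` duplicate differences `d_i` -- the usual convention for the
#' repeatability of a reference method, against which the model's SE is
#' judged (SE below twice SEL indicates an excellent model).
#'
#' @param pairs two-column matrix or data.frame of duplicate moisture
#'   determinations (percent), one pair per row, at least 2 rows
#' @return SEL in percent
#' @export
sel_from_replicates <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) < 2)
    stop("need at least 2 duplicate pairs (two columns)")
  d <- pairs[, 1] - pairs[, 2]
  sqrt(sum(d^2) / (2 * nrow(pairs)))
}

#' Full evaluation report for a fitted model
#'
#' Assembles the standard report: training-set `RC2`/`RMSEC`,
#' cross-validation `RCV2`/`RMSECV`, test-set `RP2`/`RMSEP`, `RPD` and
#' `SE`.
#'
#' @param y_train,yhat_train training references and predictions
#' @param y_test,yhat_test test references and predictions
#' @param rmsecv cross-validated RMSE at the chosen model size (optional)
#' @param rcv2 cross-validated R2 (optional; computed from `rmsecv` and the
#'   training variance when omitted)
#' @return list of class `evaluation_report`
#' @export
evaluation_report <- function(y_train, yhat_train, y_test, yhat_test,
                              rmsecv = NA_real_, rcv2 = NULL) {
  tr <- evaluate(y_train, yhat_train, "training")
  te <- evaluate(y_test, yhat_test, "test")
  if (is.null(rcv2)) {
    v <- stats::var(y_train) * (length(y_train) - 1) / length(y_train)
    rcv2 <- if (is.finite(rmsecv) && v > 0) 1 - rmsecv^2 / v else NA_real_
  }
  structure(list(rc2 = tr$r2, rmsec = tr$rmse,
                 rcv2 = rcv2, rmsecv = rmsecv,
                 rp2 = te$r2, rmsep = te$rmse,
                 rpd = te$rpd, se = te$se),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat(sprintf("  training:  RC2 = %.4f  RMSEC = %.4f\n", x$rc2, x$rmsec))
  cat(sprintf("  cross-val: RCV2 = %.4f  RMSECV = %.4f\n", x$rcv2, x$rmsecv))
  cat(sprintf("  test:      RP2 = %.4f  RMSEP = %.4f  RPD = %.2f  SE = %.4f\n",
              x$rp2, x$rmsep, x$rpd, x$se))
  invisible(x)
}

#' Train/test split
#'
#' Random split (default) or Kennard-Stone: the latter picks calibration
#' samples by the max-min Euclidean distance criterion in spectral space,
#' so the calibration set spans the data cloud.
#'
#' @param X matrix or [spectra_set] (used by Kennard-Stone)
#' @param test_fraction fraction of samples held out (default 0.25)
#' @param method `"random"` or `"kennard_stone"`
#' @param seed seed for the random method
#' @return list with integer index vectors `train` and `test`
#' @export
split_samples <- function(X, test_fraction = 0.25,
                          method = c("random", "kennard_stone"), seed = 1L) {
  method <- match.arg(method)
  if (inherits(X, "spectra_set")) X <- X$matrix
  n <- nrow(X)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  n_test <- max(1L, round(test_fraction * n))
  if (n_test >= n) stop("test fraction leaves no training samples")
  if (method == "random") {
    test <- withr::with_seed(as.integer(seed),
                             sort(sample.int(n, n_test)))
  } else {
    n_train <- n - n_test
    d2 <- as.matrix(stats::dist(X))^2
    sel <- integer(n_train)
    sel[1:2] <- as.integer(arrayInd(which.max(d2), dim(d2)))
    for (k in 3:n_train) {
      rest <- setdiff(seq_len(n), sel[seq_len(k - 1L)])
      mind <- apply(d2[rest, sel[seq_len(k - 1L)], drop = FALSE], 1, min)
      sel[k] <- rest[which.max(mind)]
    }
    test <- sort(setdiff(seq_len(n), sel))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}
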