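#' Partial least squares regression (SIMPLS)
#'
#' Fits a univariate-response PLSR model by the SIMPLS algorithm: X and y
#' are centered internally, successive weight vectors maximize covariance
#' with the response under orthogonality of the X-loadings, and the model
#' is stored both as the score-space factorization and as flattened
#' regression coefficients (intercept `b0`, per-band `b`). The two
#' prediction routes agree to numerical precision, and with `nc` equal to
#' the rank of centered X the fit coincides with ordinary least squares.
#'
#' @param X numeric matrix (samples x bands) or a [spectra_set]
#' @param y numeric response (percent moisture) or a [reference_table]
#'   aligned by `sample_id`
#' @param nc number of latent components, `1 <= nc <= min(samples-1, bands)`
#' @return an object of class `pls_model` with elements `coefficients`
#'   (`b0`, `b`), `weights` (`R`), `loadings` (`P`), `yloadings` (`Q`),
#'   `scores`, `x_center`, `y_center`, `nc`
#' @export
fit_plsr <- function(X, y, nc) {
  if (inherits(X, "spectra_set")) {
    y <- align_refs(X, y)
    X <- X$matrix
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y must be aligned")
  nc <- as.integer(nc)
  if (nc < 1 || nc > min(n - 1L, p))
    stop(sprintf("nc must lie in [1, %d]", min(n - 1L, p)))
  simpls(X, y, nc, partial = FALSE)
}

# SIMPLS core; with partial = TRUE, rank exhaustion truncates the model to
# the achieved number of components instead of erroring
simpls <- function(X, y, nc, partial = FALSE) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  S <- crossprod(Xc, yc)                 # p x 1
  R <- matrix(0, p, nc); P <- matrix(0, p, nc)
  V <- matrix(0, p, nc); Q <- numeric(nc)
  TT <- matrix(0, n, nc)
  achieved <- 0L
  ref_norm <- NULL
  for (a in seq_len(nc)) {
    r <- S
    t <- Xc %*% r
    normt <- sqrt(sum(t^2))
    if (is.null(ref_norm)) ref_norm <- max(normt, .Machine$double.xmin)
    if (normt < 1e-10 * ref_norm) {
      if (partial) break
      stop(sprintf(
        "nc = %d exceeds the rank of the centered data (failed at component %d)",
        nc, a))
    }
    t <- t / normt; r <- r / normt
    pa <- crossprod(Xc, t)
    qa <- sum(yc * t)
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- pa; V[, a] <- v
    Q[a] <- qa; TT[, a] <- t
    achieved <- a
  }
  if (achieved == 0L) {
    # response orthogonal to X (or constant): intercept-only model
    achieved <- 1L
  }
  keep <- seq_len(achieved)
  R <- R[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Q <- Q[keep]; TT <- TT[, keep, drop = FALSE]
  b <- as.numeric(R %*% Q)
  structure(list(coefficients = list(b0 = ym - sum(xm * b), b = b),
                 weights = R, loadings = P, yloadings = Q, scores = TT,
                 x_center = xm, y_center = ym, nc = achieved),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d components, %d bands\n",
              x$nc, length(x$coefficients$b)))
  invisible(x)
}

#' Predict from a PLSR model
#'
#' @param object a `pls_model`
#' @param newdata matrix or [spectra_set] with the same bands the model was
#'   fitted on
#' @param route `"coef"` (flattened coefficients, default) or `"scores"`
#'   (through the factorization); the two agree to numerical precision
#' @param ... unused
#' @return numeric vector of predictions
#' @export
predict.pls_model <- function(object, newdata, route = c("coef", "scores"),
                              ...) {
  route <- match.arg(route)
  if (inherits(newdata, "spectra_set")) newdata <- newdata$matrix
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients$b))
    stop("newdata band count does not match the model")
  if (route == "coef") {
    as.numeric(object$coefficients$b0 + newdata %*% object$coefficients$b)
  } else {
    t_new <- sweep(newdata, 2, object$x_center) %*% object$weights
    as.numeric(object$y_center + t_new %*% object$yloadings)
  }
}

# coefficients (b0, b) truncated to the first `a` components
pls_coef_at <- function(model, a) {
  b <- as.numeric(model$weights[, seq_len(a), drop = FALSE] %*%
                    model$yloadings[seq_len(a)])
  list(b0 = model$y_center - sum(model$x_center * b), b = b)
}

# deterministic fold assignment
cv_folds <- function(n, folds, seed) {
  withr::with_seed(as.integer(seed), sample(rep(seq_len(folds),
                                                length.out = n)))
}

# held-out residuals from k-fold PLS CV, one column per component count in
# `ncs` (one SIMPLS fit per fold at max(ncs), truncated coefficients for
# the smaller counts)
pls_cv_residuals <- function(X, y, ncs, folds = 10L, seed = 1L,
                             fold_id = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- min(folds, n)
  if (is.null(fold_id)) fold_id <- cv_folds(n, folds, seed)
  res <- matrix(NA_real_, n, length(ncs))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f; te <- !tr
    nc_max_f <- min(max(ncs), sum(tr) - 1L, ncol(X))
    fit <- simpls(X[tr, , drop = FALSE], y[tr], nc_max_f, partial = TRUE)
    for (j in seq_along(ncs)) {
      a <- min(ncs[j], fit$nc)
      cf <- pls_coef_at(fit, a)
      res[te, j] <- y[te] - (cf$b0 + X[te, , drop = FALSE] %*% cf$b)
    }
  }
  res
}

# pooled k-fold RMSECV per component count
pls_cv_rmse <- function(X, y, ncs, folds = 10L, seed = 1L,
                        fold_id = NULL) {
  res <- pls_cv_residuals(X, y, ncs, folds, seed, fold_id)
  sqrt(colMeans(res^2))
}

#' Select the number of PLS components by cross-validation
#'
#' Computes pooled k-fold RMSECV for `nc = 1..max_nc` and returns the
#' minimizer (ties broken toward the smallest `nc`).
#'
#' @param X matrix or [spectra_set]; `y` aligned response
#' @param y numeric response or [reference_table]
#' @param max_nc largest component count tried (capped by the data rank)
#' @param folds number of CV folds (default 10)
#' @param seed integer seed controlling the fold assignment
#' @return list with `nc` (chosen count) and `rmsecv` (curve of length
#'   `max_nc`)
#' @export
select_nc <- function(X, y, max_nc = 15L, folds = 10L, seed = 1L) {
  if (inherits(X, "spectra_set")) {
    y <- align_refs(X, y)
    X <- X$matrix
  }
  if (max_nc < 1) stop("max_nc must be >= 1")
  n <- nrow(X)
  if (folds > n) stop("more folds than samples")
  max_nc <- max(1L, min(max_nc, n - 1L, ncol(X)))
  curve <- pls_cv_rmse(X, y, seq_len(max_nc), folds, seed)
  list(nc = which.min(curve), rmsecv = curve)
}
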