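#' Spectral preprocessing operators
#'
#' Seven operators commonly used ahead of NIR calibration, all exposed
#' through a fit/apply split so that training-set statistics are learned
#' once and reused for test spectra and image pixels (no leakage):
#'
#' * `FD` -- first derivative: forward difference divided by the channel
#'   spacing; output has p-1 channels on the interval midpoints.
#' * `SD` -- second derivative: central second difference divided by the
#'   squared spacing; output has p-2 interior channels.
#' * `SG` -- Savitzky-Golay derivative: least-squares polynomial (default
#'   degree 3) over a 9-point window, evaluated as the polynomial's
#'   derivative (default order 2) at the window center; output shrinks to
#'   the p-(window-1) interior channels.
#' * `MSC` -- multiplicative scatter correction: each spectrum is regressed
#'   on the stored reference (training mean spectrum), `x ~ a + b r`, and
#'   corrected to `(x - a)/b`.
#' * `SNV` -- standard normal variate: each spectrum standardized to mean 0,
#'   sd 1 (n-1 denominator).
#' * `MC` -- mean centering by the stored training column means.
#' * `MMN` -- per-band min-max normalization by the stored training column
#'   min/max; out-of-range test values may fall outside `[0, 1]` and are
#'   not clipped.
#'
#' Row-wise operators (FD, SD, SG, SNV) store no state; derivative
#' operators shrink the wavelength grid rather than padding fabricated
#' edge values.
#'
#' @param method one of `"FD"`, `"SD"`, `"SG"`, `"MSC"`, `"SNV"`, `"MC"`,
#'   `"MMN"`, or `"none"`
#' @param train a [spectra_set] of training spectra (used by MSC/MC/MMN;
#'   required for all methods so the fit-time grid is recorded)
#' @param sg_window odd Savitzky-Golay window length in points (default 9)
#' @param sg_degree polynomial degree (default 3; must be < window)
#' @param sg_deriv derivative order, 0, 1 or 2 (default 2)
#' @return an object of class `preprocess` carrying the method, parameters
#'   and fitted state
#' @export
preprocess_fit <- function(method, train,
                           sg_window = 9L, sg_degree = 3L, sg_deriv = 2L) {
  method <- toupper(method)
  if (identical(method, "NONE")) method <- "none"
  ok <- c("FD", "SD", "SG", "MSC", "SNV", "MC", "MMN", "none")
  if (!method %in% ok)
    stop(sprintf("unknown preprocessing method '%s'", method))
  stopifnot(inherits(train, "spectra_set"))
  if (nrow(train$matrix) < 1) stop("training set is empty")
  state <- list()
  if (method == "SG") {
    sg_window <- as.integer(sg_window); sg_degree <- as.integer(sg_degree)
    sg_deriv <- as.integer(sg_deriv)
    if (sg_window %% 2L == 0L || sg_window <= sg_degree)
      stop("SG window must be odd and greater than the polynomial degree")
    if (!sg_deriv %in% 0:2) stop("SG derivative order must be 0, 1 or 2")
    if (ncol(train$matrix) < sg_window)
      stop("fewer channels than the SG window")
  }
  if (method == "MSC") state$reference <- colMeans(train$matrix)
  if (method == "MC") state$means <- colMeans(train$matrix)
  if (method == "MMN") {
    state$min <- apply(train$matrix, 2, min)
    state$max <- apply(train$matrix, 2, max)
    if (any(state$max - state$min <= 0))
      stop("MMN requires at least two distinct values per band in training")
  }
  structure(list(method = method,
                 params = list(sg_window = sg_window, sg_degree = sg_degree,
                               sg_deriv = sg_deriv),
                 state = state,
                 wavelengths = train$wavelengths),
            class = "preprocess")
}

#' @export
print.preprocess <- function(x, ...) {
  cat(sprintf("preprocess: %s (%d-channel grid)\n", x$method,
              length(x$wavelengths)))
  invisible(x)
}

# Savitzky-Golay convolution weights for derivative `deriv` at the window
# center, in index units (caller rescales by the grid spacing)
sg_weights <- function(window, degree, deriv) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:degree, "^")
  C <- solve(crossprod(A), t(A))     # (degree+1) x window
  factorial(deriv) * C[deriv + 1L, ]
}

#' Apply a fitted preprocessing operator
#'
#' @param object a fitted `preprocess` object from [preprocess_fit()]
#' @param s a [spectra_set] on the same wavelength grid the operator was
#'   fitted on
#' @param on_constant what to do when SNV meets a zero-variance spectrum or
#'   MSC a near-zero slope (|b| < 1e-12): `"error"` (default) or `"na"`,
#'   which fills the offending row with `NA` (used for pixel-wise mapping,
#'   where one bad pixel must not abort the map)
#' @return a [spectra_set]; derivative methods return a shrunk grid
#' @export
preprocess_apply <- function(object, s, on_constant = c("error", "na")) {
  stopifnot(inherits(object, "preprocess"), inherits(s, "spectra_set"))
  on_constant <- match.arg(on_constant)
  if (length(s$wavelengths) != length(object$wavelengths) ||
      max(abs(s$wavelengths - object$wavelengths)) > 1e-9)
    stop("wavelength grid does not match the grid the operator was fitted on")
  x <- s$matrix
  w <- s$wavelengths
  dl <- mean(diff(w))
  tol <- 1e-12
  bad <- rep(FALSE, nrow(x))
  out <- switch(object$method,
    none = list(x, w),
    SNV = {
      mu <- rowMeans(x)
      sdv <- apply(x, 1, stats::sd)
      bad <- sdv < tol
      sdv[bad] <- NA
      list((x - mu) / sdv, w)
    },
    MSC = {
      r <- object$state$reference
      rc <- r - mean(r)
      vr <- sum(rc^2)
      xc <- x - rowMeans(x)
      b <- as.numeric(xc %*% rc) / vr
      a <- rowMeans(x) - b * mean(r)
      bad <- abs(b) < tol
      b[bad] <- NA
      list((x - a) / b, w)
    },
    FD = {
      p <- ncol(x)
      list((x[, -1, drop = FALSE] - x[, -p, drop = FALSE]) / dl,
           (w[-1] + w[-p]) / 2)
    },
    SD = {
      p <- ncol(x)
      list((x[, -(1:2), drop = FALSE] - 2 * x[, -c(1, p), drop = FALSE] +
              x[, -((p - 1):p), drop = FALSE]) / dl^2,
           w[-c(1, p)])
    },
    SG = {
      win <- object$params$sg_window
      h <- (win - 1L) %/% 2L
      cw <- sg_weights(win, object$params$sg_degree, object$params$sg_deriv)
      p <- ncol(x)
      centers <- (h + 1L):(p - h)
      acc <- matrix(0, nrow(x), length(centers))
      for (o in seq_len(win))
        acc <- acc + cw[o] * x[, centers + (o - h - 1L), drop = FALSE]
      list(acc / dl^object$params$sg_deriv, w[centers])
    },
    MC = list(sweep(x, 2, object$state$means), w),
    MMN = list(sweep(sweep(x, 2, object$state$min), 2,
                     object$state$max - object$state$min, "/"), w))
  if (any(bad)) {
    if (on_constant == "error")
      stop(sprintf("%s failed on constant spectrum row(s): %s",
                   object$method,
                   paste(s$sample_ids[bad], collapse = ", ")))
    out[[1]][bad, ] <- NA_real_
  }
  res <- s
  res$matrix <- out[[1]]
  res$wavelengths <- out[[2]]
  colnames(res$matrix) <- format_nm(res$wavelengths)
  rownames(res$matrix) <- res$sample_ids
  res
}
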