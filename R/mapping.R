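#' Pixel-wise moisture prediction map
#'
#' Applies a trained calibration to every masked pixel of a reflectance
#' cube: trim edge bands, run the fitted preprocessing chain (training
#' statistics reused; row-wise operators applied per pixel), restrict to
#' the selected wavelengths, and predict. A pixel whose spectrum defeats a
#' per-spectrum operator (e.g. constant under SNV/MSC) is marked missing
#' and counted, never aborting the map.
#'
#' @param cube a [reflectance_cube] on the training grid (before trimming)
#' @param mask logical sample mask (`rows x cols`); defaults to
#'   [segment_sample()] output
#' @param model a `pls_model` or `rfr_model` trained on the selected bands
#' @param chain list of fitted `preprocess` objects (possibly empty),
#'   applied in order; the first must be fitted on the trimmed grid
#' @param selection a `selection_result`, or `NULL` for all post-chain
#'   bands; indices refer to the post-chain grid
#' @param trim `c(lo, hi)` nm interval passed to [trim_bands()], or `NULL`
#'   to skip trimming
#' @return object of class `moisture_map`: `values` (matrix, percent, `NA`
#'   off-mask or failed), `mask`, `n_failed`
#' @export
predict_map <- function(cube, mask = NULL, model, chain = list(),
                        selection = NULL, trim = c(960, 2489)) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (is.null(mask)) mask <- segment_sample(cube)
  if (!identical(dim(mask), dim(cube$data)[1:2]))
    stop("mask must match the cube's spatial dimensions")
  mask <- mask & cube$valid_mask
  if (!any(mask)) stop("mask is empty")
  d <- dim(cube$data)
  idx <- which(mask)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  pix <- spectra_set(flat[idx, , drop = FALSE], cube$wavelengths,
                     sprintf("px%07d", idx))
  if (!is.null(trim)) pix <- trim_bands(pix, trim[1], trim[2])
  if (inherits(chain, "preprocess")) chain <- list(chain)
  for (op in chain) pix <- preprocess_apply(op, pix, on_constant = "na")
  m <- pix$matrix
  if (!is.null(selection))
    m <- m[, selection$selected_indices, drop = FALSE]
  ok <- !apply(is.na(m), 1, any)
  pred <- rep(NA_real_, length(idx))
  if (any(ok)) pred[ok] <- predict(model, m[ok, , drop = FALSE])
  values <- matrix(NA_real_, d[1], d[2])
  values[idx] <- pred
  structure(list(values = values, mask = mask,
                 n_failed = sum(!ok)),
            class = "moisture_map")
}

#' @export
print.moisture_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("moisture_map: %d pixels, %d failed, range %.2f-%.2f %%\n",
              sum(x$mask), x$n_failed,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Render a moisture map to a raster file
#'
#' Blue-to-red colormap over `[lo, hi]` percent (red = wettest), values
#' clipped for display only; background pixels are rendered neutral grey
#' and a colorbar legend in percent is drawn alongside.
#'
#' @param map a `moisture_map`
#' @param lo,hi display range in percent; defaults to the 1st and 99th
#'   percentiles of the mapped values
#' @param out_path output PNG path
#' @param width,height device size in pixels
#' @return `out_path` invisibly
#' @export
render_map <- function(map, lo = NULL, hi = NULL, out_path,
                       width = 640L, height = 480L) {
  stopifnot(inherits(map, "moisture_map"))
  v <- map$values[map$mask]
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty map: no finite values to render")
  if (is.null(lo)) lo <- as.numeric(stats::quantile(v, 0.01))
  if (is.null(hi)) hi <- as.numeric(stats::quantile(v, 0.99))
  if (lo >= hi) {
    # constant map: widen the display range symmetrically
    lo <- lo - 0.5; hi <- hi + 0.5
  }
  pal <- grDevices::colorRampPalette(
    c("#313695", "#4575b4", "#74add1", "#ffffbf", "#f46d43", "#d73027",
      "#a50026"))(256)
  clipped <- pmin(pmax(map$values, lo), hi)
  z <- t(clipped)[, nrow(clipped):1, drop = FALSE]   # image() orientation
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1), widths = c(5, 1))
  op <- graphics::par(mar = c(2, 2, 2, 1))
  graphics::image(z, col = pal, zlim = c(lo, hi), axes = FALSE,
                  useRaster = TRUE, main = "Predicted moisture (%)")
  graphics::par(mar = c(2, 1, 2, 3))
  leg <- seq(lo, hi, length.out = 256)
  graphics::image(1, leg, matrix(leg, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(4, las = 1)
  graphics::mtext("%", side = 3, line = 0.3)
  graphics::par(op)
  invisible(out_path)
}

#' Write map values as a CSV matrix
#'
#' @param map a `moisture_map`
#' @param path output path; `NA` marks off-sample pixels
#' @return `path` invisibly
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
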