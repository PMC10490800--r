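#' Default NIR wavelength grid
#'
#' Channel centers of the imaging spectrometer emulated throughout the
#' package: `n` channels linearly spanning `from`--`to` nm. The default
#' (256 channels, 935.5--2539 nm) matches the acquisition range of a
#' push-broom NIR hyperspectral system with ~6.3 nm spectral resolution.
#'
#' @param n number of channels
#' @param from,to first and last channel center, in nm
#' @return numeric vector of strictly increasing, uniformly spaced
#'   wavelengths (nm)
#' @export
#' @examples
#' g <- default_grid()
#' length(g)   # 256
#' range(g)    # 935.5 2539
default_grid <- function(n = 256L, from = 935.5, to = 2539) {
  stopifnot(n >= 2L, from < to)
  seq(from, to, length.out = n)
}

#' @keywords internal
check_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L)
    stop("wavelength grid must be a numeric vector of length >= 2")
  d <- diff(wavelengths)
  if (any(d <= 0)) stop("wavelength grid must be strictly increasing")
  if (diff(range(d)) > 1e-9)
    stop("wavelength grid must be uniformly spaced (tolerance 1e-9 nm)")
  invisible(wavelengths)
}

#' Spectra set: samples x bands matrix tied to a wavelength grid
#'
#' The central tabular container of the package: one row per sample, one
#' column per spectral channel, plus the wavelength grid (nm) and unique
#' sample identifiers.
#'
#' @param x numeric matrix, samples in rows, bands in columns
#' @param wavelengths numeric vector of channel centers (nm), length =
#'   `ncol(x)`
#' @param sample_ids character vector of unique row labels; defaults to
#'   `S001, S002, ...`
#' @return an object of class `spectra_set`
#' @export
spectra_set <- function(x, wavelengths, sample_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(wavelengths) != ncol(x))
    stop("length(wavelengths) must equal ncol(x)")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(nrow(x)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(x))
    stop("length(sample_ids) must equal nrow(x)")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (anyNA(x))
    stop("spectra_set does not allow missing values")
  rownames(x) <- sample_ids
  colnames(x) <- format_nm(wavelengths)
  structure(list(matrix = x,
                 wavelengths = as.numeric(wavelengths),
                 sample_ids = sample_ids),
            class = "spectra_set")
}

format_nm <- function(w) sprintf("%.1f", w)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$matrix)

#' Trim low signal-to-noise edge bands
#'
#' Retains exactly the channels whose center falls in the closed interval
#' `[lo_nm, hi_nm]`. On the default 256-channel grid, trimming to
#' `[960, 2489]` nm retains 244 bands (the first and last low-SNR channels
#' of the detector are discarded before modeling).
#'
#' @param s a [spectra_set]
#' @param lo_nm,hi_nm interval endpoints in nm (closed interval, endpoints
#'   kept)
#' @return a [spectra_set] restricted to the retained channels
#' @export
trim_bands <- function(s, lo_nm = 960, hi_nm = 2489) {
  stopifnot(inherits(s, "spectra_set"))
  if (lo_nm >= hi_nm) stop("lo_nm must be < hi_nm")
  keep <- s$wavelengths >= lo_nm & s$wavelengths <= hi_nm
  if (!any(keep)) stop("no channel falls inside [lo_nm, hi_nm]")
  spectra_set(s$matrix[, keep, drop = FALSE], s$wavelengths[keep],
              s$sample_ids)
}

#' Reference moisture table
#'
#' @param sample_ids unique sample labels
#' @param moisture moisture content in percent (0 <= H < 100)
#' @return data.frame of class `reference_table` with columns `sample_id`,
#'   `moisture`
#' @export
reference_table <- function(sample_ids, moisture) {
  sample_ids <- as.character(sample_ids)
  moisture <- as.numeric(moisture)
  if (length(sample_ids) != length(moisture))
    stop("sample_ids and moisture must have the same length")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (any(!is.finite(moisture)) || any(moisture < 0) || any(moisture >= 100))
    stop("moisture must be finite, >= 0 and < 100 percent")
  structure(data.frame(sample_id = sample_ids, moisture = moisture,
                       stringsAsFactors = FALSE),
            class = c("reference_table", "data.frame"))
}

#' Write / read a spectra set as CSV
#'
#' Layout: first column `sample_id`, then one column per wavelength; the
#' header row carries the wavelengths in nm with one decimal.
#'
#' @param s a [spectra_set]
#' @param path file path
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [spectra_set]
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  df <- data.frame(sample_id = s$sample_ids, s$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  w <- as.numeric(names(df)[-1])
  if (anyNA(w)) stop("header must carry numeric wavelengths in nm")
  spectra_set(as.matrix(df[, -1, drop = FALSE]), w, df$sample_id)
}

#' @keywords internal
align_refs <- function(s, refs) {
  stopifnot(inherits(s, "spectra_set"))
  if (inherits(refs, "reference_table") || is.data.frame(refs)) {
    i <- match(s$sample_ids, refs$sample_id)
    if (anyNA(i)) stop("reference table is missing some spectra sample_ids")
    as.numeric(refs$moisture[i])
  } else {
    y <- as.numeric(refs)
    if (length(y) != nrow(s$matrix))
      stop("reference values must align with spectra rows")
    y
  }
}
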