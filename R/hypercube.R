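#' Raw and reflectance hyperspectral cubes
#'
#' `raw_cube` holds detector counts as a `rows x cols x bands` array tied to
#' a wavelength grid; `reflectance_cube` holds black/white-corrected
#' reflectance plus a mask of usable pixels.
#'
#' @param data numeric `rows x cols x bands` array
#' @param wavelengths channel centers in nm, length = number of bands
#' @param interleave storage order used when the cube is written to disk
#' @return an object of class `raw_cube`
#' @export
raw_cube <- function(data, wavelengths, interleave = c("bil", "bip", "bsq")) {
  interleave <- match.arg(interleave)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("cube data must be a 3-D array")
  if (any(dim(data) <= 0)) stop("all cube dimensions must be > 0")
  if (dim(data)[3] != length(wavelengths))
    stop("number of bands must equal the wavelength grid length")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 interleave = interleave),
            class = "raw_cube")
}

#' @rdname raw_cube
#' @param valid_mask logical `rows x cols` matrix of usable pixels
#' @export
reflectance_cube <- function(data, wavelengths, valid_mask = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("cube data must be a 3-D array")
  if (dim(data)[3] != length(wavelengths))
    stop("number of bands must equal the wavelength grid length")
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  if (!identical(dim(valid_mask), dim(data)[1:2]))
    stop("valid_mask must match the cube's spatial dimensions")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 valid_mask = valid_mask),
            class = "reflectance_cube")
}

#' @export
print.raw_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("raw_cube: %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$interleave))
  invisible(x)
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("reflectance_cube: %d x %d pixels, %d bands, %d valid pixels\n",
              d[1], d[2], d[3], sum(x$valid_mask)))
  invisible(x)
}

envi_dtype <- c("4" = 4L, "5" = 8L, "2" = 2L, "12" = 2L)  # bytes per value

#' Read / write ENVI-format hyperspectral cubes
#'
#' Plain ENVI dialect: a text header declaring `samples` (columns), `lines`
#' (rows), `bands`, `data type` (2/12 = 16-bit int, 4 = float32, 5 =
#' float64), `interleave` (bsq/bil/bip), `byte order` (little-endian only)
#' and a `wavelength = {...}` list; a raw binary data file. `write_envi`
#' defaults to BIL, float64, so a write/read round trip reproduces the cube
#' exactly.
#'
#' @param header_path path to the `.hdr` text header
#' @param data_path path to the binary data file
#' @return `read_envi` returns a [raw_cube]; `write_envi` returns
#'   `header_path` invisibly
#' @export
read_envi <- function(header_path, data_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (!grepl("^ENVI", txt[1])) stop("not an ENVI header (missing ENVI magic)")
  # join continuation of {...} blocks
  joined <- paste(txt[-1], collapse = "\n")
  get_field <- function(name, required = TRUE) {
    m <- regmatches(joined, regexpr(
      paste0("(?mi)^", name, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"), joined,
      perl = TRUE))
    if (!length(m)) {
      if (required) stop(sprintf("ENVI header is missing '%s'", name))
      return(NULL)
    }
    v <- sub(paste0("(?i)^", name, "\\s*=\\s*"), "", m, perl = TRUE)
    gsub("[{}]", "", v)
  }
  samples <- as.integer(get_field("samples"))
  lines_n <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- as.character(as.integer(get_field("data type")))
  interleave <- tolower(trimws(get_field("interleave")))
  byte_order <- get_field("byte order", required = FALSE)
  if (!is.null(byte_order) && as.integer(byte_order) != 0L)
    stop("only little-endian (byte order = 0) ENVI files are supported")
  wl_txt <- get_field("wavelength")
  wl <- as.numeric(strsplit(wl_txt, "[,\n]")[[1]] |> trimws() |>
                     (\(z) z[nzchar(z)])())
  if (!length(wl) || anyNA(wl))
    stop("ENVI header is missing a usable wavelength list")
  if (length(wl) != bands)
    stop("wavelength list length does not match the declared band count")
  if (!dtype %in% names(envi_dtype))
    stop(sprintf("unsupported ENVI data type %s", dtype))
  bytes <- envi_dtype[[dtype]]
  expected <- as.numeric(samples) * lines_n * bands * bytes
  actual <- file.info(data_path)$size
  if (is.na(actual) || actual != expected)
    stop(sprintf("binary size (%s bytes) does not match header dims (%s bytes expected)",
                 format(actual), format(expected)))
  n <- samples * lines_n * bands
  con <- file(data_path, "rb"); on.exit(close(con))
  vec <- if (bytes == 8 && dtype == "5") {
    readBin(con, "double", n, size = 8, endian = "little")
  } else if (dtype == "4") {
    readBin(con, "double", n, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n, size = 2, endian = "little",
            signed = dtype == "2")
  }
  arr <- switch(interleave,
    bsq = aperm(array(vec, c(samples, lines_n, bands)), c(2, 1, 3)),
    bil = aperm(array(vec, c(samples, bands, lines_n)), c(3, 1, 2)),
    bip = aperm(array(vec, c(bands, samples, lines_n)), c(3, 2, 1)),
    stop(sprintf("unsupported interleave '%s'", interleave)))
  raw_cube(arr, wl, interleave)
}

#' @rdname read_envi
#' @param cube a [raw_cube] (or [reflectance_cube]; written as float data)
#' @param data_type ENVI data type code to write: 5 (float64, default,
#'   lossless) or 4 (float32)
#' @export
write_envi <- function(cube, header_path, data_path, data_type = 5L) {
  stopifnot(inherits(cube, "raw_cube") || inherits(cube, "reflectance_cube"))
  interleave <- if (!is.null(cube$interleave)) cube$interleave else "bil"
  d <- dim(cube$data)
  arr <- cube$data
  vec <- switch(interleave,
    bsq = as.vector(aperm(arr, c(2, 1, 3))),
    bil = as.vector(aperm(arr, c(2, 3, 1))),
    bip = as.vector(aperm(arr, c(3, 2, 1))))
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", as.integer(data_type)),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           paste0("wavelength = {", paste(format(cube$wavelengths,
                                                 trim = TRUE), collapse = ", "),
                  "}"))
  writeLines(hdr, header_path)
  con <- file(data_path, "wb"); on.exit(close(con))
  writeBin(as.double(vec), con, size = envi_dtype[[as.character(data_type)]],
           endian = "little")
  invisible(header_path)
}

#' Black/white reflectance correction
#'
#' Converts raw detector counts to reflectance with the standard two-point
#' calibration `I = (I0 - IB) / (IW - IB)`, where `I0` is the raw cube,
#' `IB` the all-black (lens cap) frame and `IW` the all-white (99 percent
#' reflectance panel) frame. Pixels where `IW - IB <= 0` in any band are
#' excluded from the valid mask instead of producing non-finite values.
#'
#' @param raw a [raw_cube] of detector counts
#' @param dark,white calibration cubes with the same dimensions as `raw`
#'   (or `rows x cols` matrices recycled over bands, or per-band vectors
#'   recycled over pixels)
#' @return a [reflectance_cube]
#' @export
correct_reflectance <- function(raw, dark, white) {
  stopifnot(inherits(raw, "raw_cube"))
  d <- dim(raw$data)
  expand <- function(x, what) {
    if (inherits(x, "raw_cube")) x <- x$data
    if (is.array(x) && length(dim(x)) == 3L) {
      if (!identical(dim(x), d)) stop(sprintf("%s frame dims must match the cube", what))
      return(x)
    }
    if (is.matrix(x)) {
      if (!identical(dim(x), d[1:2])) stop(sprintf("%s frame dims must match the cube", what))
      return(array(rep(as.vector(x), d[3]), d))
    }
    if (length(x) == d[3])
      return(array(rep(as.numeric(x), each = d[1] * d[2]), d))
    stop(sprintf("%s frame has incompatible dimensions", what))
  }
  db <- expand(dark, "dark"); wb <- expand(white, "white")
  denom <- wb - db
  bad_any <- apply(denom <= 0, c(1, 2), any)
  if (all(bad_any))
    stop("degenerate calibration: white <= dark for every pixel")
  out <- (raw$data - db) / denom
  if (any(bad_any)) {
    idx <- which(bad_any)
    for (b in seq_len(d[3])) {
      plane <- out[, , b]; plane[idx] <- NA_real_; out[, , b] <- plane
    }
  }
  reflectance_cube(out, raw$wavelengths, valid_mask = !bad_any)
}

#' Segment the sample region of a reflectance cube
#'
#' Default criterion: automatic two-class (Otsu) intensity threshold on the
#' band-averaged reflectance image, keeping the bright class, then removal
#' of connected components smaller than `min_size` pixels.
#'
#' @param cube a [reflectance_cube]
#' @param min_size smallest connected component (pixels) kept
#' @param bright_sample if `TRUE` (default) the sample is the bright class
#'   against a darker background; set `FALSE` for the converse
#' @return logical `rows x cols` mask of sample pixels
#' @export
segment_sample <- function(cube, min_size = 10L, bright_sample = TRUE) {
  stopifnot(inherits(cube, "reflectance_cube"))
  m <- apply(cube$data, c(1, 2), mean)
  m[!cube$valid_mask] <- NA
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) < 1e-10)
    stop("no sample detected: band-averaged image is uniform")
  scaled <- (m - rng[1]) / diff(rng)
  scaled[is.na(scaled)] <- 0
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- if (bright_sample) scaled > thr else scaled < thr
  mask[!cube$valid_mask] <- FALSE
  if (min_size > 1 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= min_size])
    mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) stop("no sample detected")
  mask
}

#' Mean spectrum over a pixel mask
#'
#' Averages the spectra of all masked pixels per band -- the operation that
#' turns a segmented sample region into one calibration spectrum.
#'
#' @param cube a [reflectance_cube]
#' @param mask logical `rows x cols` matrix; must be nonempty and lie
#'   within the cube's valid mask
#' @return numeric vector of length `bands`
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (!identical(dim(mask), dim(cube$data)[1:2]))
    stop("mask must match the cube's spatial dimensions")
  if (!any(mask)) stop("mask is empty")
  if (any(mask & !cube$valid_mask))
    stop("mask includes pixels outside the cube's valid mask")
  idx <- which(mask)
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}

#' Extract one mean spectrum per pellet from a scene
#'
#' Convenience wrapper used by the pipeline: segments the corrected scene,
#' labels connected pellet regions, and averages each region into a row of
#' a [spectra_set].
#'
#' @param cube a [reflectance_cube]
#' @param mask optional precomputed segmentation mask
#' @param min_size passed to [segment_sample()]
#' @return a [spectra_set] with one row per connected region, ordered by
#'   region label (raster order of first pixel)
#' @export
extract_mean_spectra <- function(cube, mask = NULL, min_size = 10L) {
  if (is.null(mask)) mask <- segment_sample(cube, min_size = min_size)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  ids <- sort(unique(labm[labm > 0]))
  rows <- t(vapply(ids, function(i) mean_spectrum(cube, labm == i),
                   numeric(dim(cube$data)[3])))
  spectra_set(rows, cube$wavelengths, sprintf("S%03d", seq_along(ids)))
}
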