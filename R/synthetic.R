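#' Simulation configuration for synthetic NIR pellet-feed data
#'
#' Collects the knobs of the spectral forward model used by
#' [generate_spectra()] and [generate_scene()]. The model emulates diffuse
#' reflectance of pellet feed in the 935.5--2539 nm range: a smooth
#' baseline, water absorption dips at 1450 and 1940 nm proportional to
#' moisture content, nuisance constituent dips (protein/fat/cellulose-like
#' bands at 1100, 1720 and 2300 nm), per-sample multiplicative scatter and
#' additive offset (the distortions MSC/SNV are designed to remove), a
#' per-sample low-order baseline perturbation, and iid channel noise.
#'
#' @param n_samples number of samples (>= 4)
#' @param moisture_range target moisture interval `(lo, hi)` in percent
#' @param other_fraction fraction of samples drawn outside `moisture_range`
#'   (the "Other" bin of the reference population)
#' @param water_peaks matrix-like with columns `center`, `width`, `amplitude`
#'   (nm, nm, reflectance units per percent moisture); the amplitudes are the
#'   depths of the water absorption dips
#' @param nuisance_peaks same layout for moisture-independent dry-matter
#'   constituents (protein/fat/cellulose-like bands); per-sample relative
#'   concentrations are drawn Normal(1, 0.1) -- a manufactured feed's
#'   composition varies by roughly ten percent, and the resulting stable
#'   absorption signature is what lets scatter-sensitive models anchor the
#'   per-sample gain
#' @param scatter_sd sd of the per-sample multiplicative gain (gain ~
#'   Normal(1, scatter_sd))
#' @param offset_sd sd of the per-sample additive offset (reflectance units)
#' @param baseline_coeffs_sd sds of the per-sample perturbation of the
#'   quadratic baseline, one per polynomial degree 0..2
#' @param noise_sd sd of iid per-channel noise (reflectance units)
#' @param seed integer seed; fixing it fixes every generated output
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_samples = 144L,
                       moisture_range = c(8, 14),
                       other_fraction = 0.1,
                       water_peaks = cbind(center = c(1450, 1940),
                                           width = c(45, 55),
                                           amplitude = c(0.030, 0.040)),
                       nuisance_peaks = cbind(center = c(1100, 1720, 2300),
                                              width = c(40, 50, 60),
                                              amplitude = c(0.030, 0.025, 0.030)),
                       scatter_sd = 0.05,
                       offset_sd = 0.02,
                       baseline_coeffs_sd = c(0.010, 0.005, 0.003),
                       noise_sd = 0.002,
                       seed = 20230901L) {
  if (n_samples < 4) stop("n_samples must be >= 4")
  if (moisture_range[1] >= moisture_range[2])
    stop("invalid moisture interval: lo must be < hi")
  water_peaks <- as.matrix(water_peaks)
  nuisance_peaks <- as.matrix(nuisance_peaks)
  if (any(water_peaks[, "width"] <= 0) || any(nuisance_peaks[, "width"] <= 0))
    stop("peak widths must be > 0")
  if (other_fraction < 0 || other_fraction > 1)
    stop("other_fraction must lie in [0, 1]")
  if (scatter_sd < 0 || offset_sd < 0 || noise_sd < 0 ||
      any(baseline_coeffs_sd < 0))
    stop("all standard deviations must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 moisture_range = as.numeric(moisture_range),
                 other_fraction = other_fraction,
                 water_peaks = water_peaks,
                 nuisance_peaks = nuisance_peaks,
                 scatter_sd = scatter_sd,
                 offset_sd = offset_sd,
                 baseline_coeffs_sd = as.numeric(baseline_coeffs_sd),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate laboratory reference moisture values
#'
#' Emulates a moisture-controlled sample population: a fraction
#' `1 - other_fraction` of samples falls in `range` (default 8--14 percent)
#' and the rest ("Other") below it, keeping the whole population under the
#' upper bound.
#'
#' @param n number of samples (>= 4)
#' @param range main moisture interval `(lo, hi)` in percent
#' @param other_fraction fraction of samples outside `range`
#' @param seed integer seed
#' @return a [reference_table] with `n` rows
#' @export
generate_reference_values <- function(n = 144L, range = c(8, 14),
                                      other_fraction = 0.1, seed = 20230901L) {
  if (n < 4) stop("n must be >= 4")
  if (range[1] >= range[2]) stop("invalid moisture interval: lo must be < hi")
  if (other_fraction < 0 || other_fraction > 1)
    stop("other_fraction must lie in [0, 1]")
  n <- as.integer(n)
  n_other <- as.integer(round(other_fraction * n))
  withr::with_seed(as.integer(seed), {
    main <- stats::runif(n - n_other, range[1], range[2])
    lo_other <- max(0.5, range[1] - 4)
    other <- if (n_other > 0) stats::runif(n_other, lo_other, range[1] - 1e-6)
             else numeric(0)
    h <- c(main, other)
    h <- h[sample.int(n)]
    reference_table(sprintf("S%03d", seq_len(n)), h)
  })
}

gauss_peak <- function(w, center, width) exp(-0.5 * ((w - center) / width)^2)

# fixed quadratic baseline on a normalized wavelength axis
baseline_mean <- function(w) {
  u <- (w - mean(range(w))) / (diff(range(w)) / 2)
  0.72 - 0.05 * u - 0.03 * u^2
}

#' Generate synthetic NIR spectra with ground truth
#'
#' Forward model per sample i:
#' \deqn{x_i(\lambda) = g_i [b(\lambda) + d_i(\lambda) + H_i q(\lambda) +
#'   \sum_k c_{ik} n_k(\lambda)] + o_i + \epsilon_i(\lambda)}
#' where `b` is the mean quadratic baseline, `d_i` a per-sample low-order
#' baseline perturbation, `q` the (negative) water absorption profile with
#' Gaussian dips at 1450/1940 nm, `n_k` nuisance constituent profiles,
#' `g_i ~ N(1, scatter_sd)` and `o_i ~ N(0, offset_sd)` the multiplicative
#' scatter and offset, and `eps` iid channel noise. With every noise term
#' zero the map from moisture `H` to spectrum is exactly affine, and the
#' recorded ground-truth coefficients are `q(lambda)`.
#'
#' @param refs a [reference_table] of moisture values (percent)
#' @param grid wavelength grid in nm (see [default_grid()])
#' @param cfg a [sim_config]
#' @return list with elements `spectra` (a [spectra_set], reflectance scale)
#'   and `truth` (list: `true_coefficients` per band, plus the per-sample
#'   gains/offsets used)
#' @export
generate_spectra <- function(refs, grid = default_grid(), cfg = sim_config()) {
  stopifnot(nrow(refs) >= 1)
  check_grid(grid)
  peaks <- rbind(cfg$water_peaks, cfg$nuisance_peaks)
  if (any(peaks[, "center"] < min(grid)) || any(peaks[, "center"] > max(grid)))
    stop("configured peak center lies outside the wavelength grid span")
  n <- nrow(refs)
  p <- length(grid)
  h <- refs$moisture

  # water absorption profile: dips, hence negative contribution per percent H
  q <- -rowSums(sapply(seq_len(nrow(cfg$water_peaks)), function(k)
    cfg$water_peaks[k, "amplitude"] *
      gauss_peak(grid, cfg$water_peaks[k, "center"], cfg$water_peaks[k, "width"])))
  nuis <- sapply(seq_len(nrow(cfg$nuisance_peaks)), function(k)
    -cfg$nuisance_peaks[k, "amplitude"] *
      gauss_peak(grid, cfg$nuisance_peaks[k, "center"],
                 cfg$nuisance_peaks[k, "width"]))   # p x K
  b <- baseline_mean(grid)
  u <- (grid - mean(range(grid))) / (diff(range(grid)) / 2)

  withr::with_seed(cfg$seed, {
    conc <- matrix(stats::rnorm(n * ncol(nuis), 1, 0.1), n)  # dry matter
    gain <- stats::rnorm(n, 1, cfg$scatter_sd)
    offset <- stats::rnorm(n, 0, cfg$offset_sd)
    bpert <- matrix(stats::rnorm(n * 3), n) %*%
      diag(cfg$baseline_coeffs_sd, 3)                        # per-sample drift
    noise <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n)
    drift <- bpert %*% rbind(rep(1, p), u, u^2)
    clean <- drift + outer(h, q) + conc %*% t(nuis) +
      matrix(b, n, p, byrow = TRUE)
    x <- clean * gain + offset + noise
  })
  truth <- list(true_coefficients = as.numeric(q),
                gain = gain, offset = offset,
                baseline = b, nuisance_profiles = nuis)
  list(spectra = spectra_set(x, grid, refs$sample_id), truth = truth)
}

# smooth low-frequency random field with given sd, deterministic under the
# caller's RNG state
smooth_field <- function(rows, cols, sd = 0.3, n_waves = 4L) {
  if (sd == 0) return(matrix(0, rows, cols))
  rr <- matrix(seq_len(rows) / rows, rows, cols)
  cc <- matrix(rep(seq_len(cols) / cols, each = rows), rows, cols)
  f <- matrix(0, rows, cols)
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(1, 0, 2 * pi); a <- stats::rnorm(1)
    f <- f + a * sin(2 * pi * (fx * rr + fy * cc) + ph)
  }
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f * (sd / s)
  f - mean(f)
}

#' Generate a synthetic hyperspectral scene with calibration frames
#'
#' Builds a raw detector-count cube containing one elliptical pellet region
#' per reference sample (arranged on a grid), a dark background, and the
#' matching all-black (sensor floor) and all-white (99 percent reflectance
#' panel) calibration cubes, such that black/white correction recovers the
#' reflectance scene. Pellet pixels carry the sample's spectrum from the
#' same forward model as [generate_spectra()], with a smooth spatial
#' moisture perturbation (sd 0.3 percentage points) so distribution maps
#' show within-pellet structure.
#'
#' @param refs a [reference_table]; one pellet per row
#' @param grid wavelength grid (nm)
#' @param cfg a [sim_config]
#' @param shape `c(rows, cols)` of the scene
#' @param field_sd sd of the within-pellet moisture field, percentage points
#' @return list with `raw`, `dark`, `white` ([raw_cube]s) and `truth`
#'   (list: `sample_mask` logical matrix, `pellet_id` integer matrix,
#'   `per_pixel_moisture` matrix with `NA` off-pellet, `true_coefficients`)
#' @export
generate_scene <- function(refs, grid = default_grid(), cfg = sim_config(),
                           shape = c(120L, 160L), field_sd = 0.3) {
  check_grid(grid)
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  if (rows <= 0 || cols <= 0) stop("rows and cols must be > 0")
  k <- nrow(refs)
  # pellet layout: k cells on a near-square grid
  gr <- max(1L, floor(sqrt(k * rows / cols)))
  gc <- ceiling(k / gr)
  if (rows / gr < 8 || cols / gc < 8)
    stop("shape too small to hold an elliptical pellet region per sample")
  ch <- rows / gr; cw <- cols / gc

  spec <- generate_spectra(refs, grid, cfg)
  p <- length(grid)
  q <- spec$truth$true_coefficients

  pellet_id <- matrix(0L, rows, cols)
  for (i in seq_len(k)) {
    ci <- (i - 1) %/% gc + 1; cj <- (i - 1) %% gc + 1
    y0 <- (ci - 0.5) * ch; x0 <- (cj - 0.5) * cw
    ry <- 0.38 * ch; rx <- 0.38 * cw
    yy <- matrix(seq_len(rows), rows, cols)
    xx <- matrix(rep(seq_len(cols), each = rows), rows, cols)
    inside <- ((yy - y0) / ry)^2 + ((xx - x0) / rx)^2 <= 1
    pellet_id[inside] <- i
  }
  mask <- pellet_id > 0L

  withr::with_seed(cfg$seed + 1L, {
    dh <- smooth_field(rows, cols, field_sd)
    hpix <- matrix(NA_real_, rows, cols)
    hpix[mask] <- refs$moisture[pellet_id[mask]] + dh[mask]
    refl <- array(0, c(rows, cols, p))
    # background: low, spectrally flat reflectance
    bg_noise <- matrix(stats::rnorm(sum(!mask) * p, 0, cfg$noise_sd),
                       sum(!mask), p)
    idx_bg <- which(!mask)
    # per-pixel pellet spectra: the sample's spectrum with its water term
    # re-evaluated at the pixel's perturbed moisture, plus pixel noise
    sample_part <- spec$spectra$matrix -
      outer(refs$moisture * spec$truth$gain, q)           # n x p
    idx_fg <- which(mask)
    npix <- length(idx_fg)
    fg <- sample_part[pellet_id[idx_fg], , drop = FALSE] +
      outer(hpix[idx_fg] * spec$truth$gain[pellet_id[idx_fg]], q) +
      matrix(stats::rnorm(npix * p, 0, cfg$noise_sd), npix, p)
    for (b in seq_len(p)) {
      plane <- matrix(0.08, rows, cols)
      plane[idx_bg] <- 0.08 + bg_noise[, b]
      plane[idx_fg] <- fg[, b]
      refl[, , b] <- plane
    }
  })

  dark_level <- 120; white_level <- 3200 + 400 * cos(2 * pi * (grid - min(grid)) /
                                                       diff(range(grid)))
  dark <- array(dark_level, c(rows, cols, p))
  white <- array(rep(white_level + dark_level, each = rows * cols),
                 c(rows, cols, p))
  raw <- sweep(refl, 3, white_level, "*") + dark_level

  truth <- list(sample_mask = mask, pellet_id = pellet_id,
                per_pixel_moisture = hpix,
                true_coefficients = q,
                sample_spectra = spec$spectra,
                gain = spec$truth$gain)
  list(raw = raw_cube(raw, grid),
       dark = raw_cube(dark, grid),
       white = raw_cube(white, grid),
       truth = truth)
}
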