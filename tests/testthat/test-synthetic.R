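test_that("reference values honor the population contract and determinism", {
  r1 <- generate_reference_values(144, c(8, 14), other_fraction = 0.1,
                                  seed = 1)
  expect_equal(nrow(r1), 144)
  expect_gte(mean(r1$moisture >= 8 & r1$moisture <= 14), 0.9)
  expect_true(all(r1$moisture < 14))

  r2 <- generate_reference_values(144, c(8, 14), other_fraction = 0.1,
                                  seed = 1)
  expect_identical(r1, r2)

  r3 <- generate_reference_values(4, other_fraction = 0)
  expect_true(all(r3$moisture >= 8 & r3$moisture <= 14))

  expect_error(generate_reference_values(3), "n must be")
  expect_error(generate_reference_values(10, range = c(14, 8)), "lo must be")
})

test_that("noise-free spectra are exactly affine in moisture", {
  refs <- generate_reference_values(40, seed = 3)
  cfg <- sim_config(noise_sd = 0, scatter_sd = 0, offset_sd = 0,
                    baseline_coeffs_sd = c(0, 0, 0), seed = 3)
  gen <- generate_spectra(refs, default_grid(), cfg)
  # a full-rank linear regressor recovers moisture perfectly
  X <- gen$spectra$matrix[, seq(1, 256, by = 8)]
  fit <- stats::lm(refs$moisture ~ X)
  expect_equal(unname(summary(fit)$r.squared), 1, tolerance = 1e-9)

  # equal moisture (and zero per-sample randomness apart from constituents)
  cfg2 <- sim_config(noise_sd = 0, scatter_sd = 0, offset_sd = 0,
                     baseline_coeffs_sd = c(0, 0, 0),
                     nuisance_peaks = cbind(center = 1720, width = 50,
                                            amplitude = 0),
                     seed = 4)
  refs2 <- reference_table(c("a", "b"), c(10, 10))
  gen2 <- generate_spectra(refs2, default_grid(), cfg2)
  expect_equal(gen2$spectra$matrix[1, ], gen2$spectra$matrix[2, ])

  # ground truth coefficients have one entry per band
  expect_length(gen$truth$true_coefficients, 256)
})

test_that("spectra generation is bit-for-bit reproducible and validated", {
  refs <- generate_reference_values(10, seed = 5)
  g1 <- generate_spectra(refs, default_grid(), sim_config(seed = 9))
  g2 <- generate_spectra(refs, default_grid(), sim_config(seed = 9))
  expect_identical(g1$spectra$matrix, g2$spectra$matrix)

  short_grid <- seq(1000, 1400, length.out = 64)
  expect_error(generate_spectra(refs, short_grid, sim_config()),
               "outside the wavelength grid")
})

test_that("scene calibration frames satisfy the correction identity", {
  refs <- generate_reference_values(4, seed = 2)
  sc <- generate_scene(reference_table(refs$sample_id[1:2],
                                       refs$moisture[1:2]),
                       shape = c(40, 60))
  one <- correct_reflectance(sc$white, sc$dark, sc$white)
  expect_true(all(abs(one$data[one$valid_mask] - 1) < 1e-12))
  zero <- correct_reflectance(sc$dark, sc$dark, sc$white)
  expect_true(all(abs(zero$data[zero$valid_mask]) < 1e-12))
})

test_that("scene segmentation recovers the ground-truth mask", {
  refs <- generate_reference_values(4, seed = 6)
  sc <- generate_scene(reference_table(refs$sample_id[1:2],
                                       refs$moisture[1:2]),
                       shape = c(60, 80))
  refl <- correct_reflectance(sc$raw, sc$dark, sc$white)
  mask <- segment_sample(refl)
  truth <- sc$truth$sample_mask
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)
})

test_that("scene shape and configuration are validated", {
  refs <- reference_table("a", 10)
  expect_error(generate_scene(refs, shape = c(0, 50)), "must be > 0")
  expect_error(generate_scene(refs, shape = c(5, 5)), "too small")
})

test_that("pellet mean spectra track the generating sample spectra", {
  refs <- generate_reference_values(4, seed = 8)
  cfg <- sim_config(seed = 8)
  sc <- generate_scene(reference_table(refs$sample_id[1],
                                       refs$moisture[1]),
                       cfg = cfg, shape = c(60, 80), field_sd = 0)
  refl <- correct_reflectance(sc$raw, sc$dark, sc$white)
  m <- mean_spectrum(refl, sc$truth$sample_mask)
  target <- sc$truth$sample_spectra$matrix[1, ]
  npix <- sum(sc$truth$sample_mask)
  # pixel noise averages out; sample-level channel noise is shared
  expect_lt(max(abs(m - target)), 4 * cfg$noise_sd / sqrt(npix) +
              4 * cfg$noise_sd)
})
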