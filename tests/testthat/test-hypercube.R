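test_that("ENVI write/read round trip is exact for every interleave", {
  for (il in c("bil", "bsq", "bip")) {
    cube <- tiny_cube(4, 5, 6)
    cube$interleave <- il
    hdr <- withr::local_tempfile(fileext = ".hdr")
    dat <- withr::local_tempfile(fileext = ".dat")
    write_envi(cube, hdr, dat)
    back <- read_envi(hdr, dat)
    expect_identical(back$data, cube$data, label = il)
    expect_equal(back$wavelengths, cube$wavelengths)
  }
})

test_that("ENVI header/binary inconsistencies are rejected", {
  cube <- tiny_cube(3, 4, 5)
  hdr <- withr::local_tempfile(fileext = ".hdr")
  dat <- withr::local_tempfile(fileext = ".dat")
  write_envi(cube, hdr, dat)

  # declared bands exceed what the binary holds
  txt <- readLines(hdr)
  txt <- sub("^bands = 5", "bands = 6", txt)
  txt <- sub("wavelength = \\{", "wavelength = {1, ", txt)
  hdr2 <- withr::local_tempfile(fileext = ".hdr")
  writeLines(txt, hdr2)
  expect_error(read_envi(hdr2, dat), "does not match")

  # wavelength list missing entirely
  txt3 <- readLines(hdr)
  txt3 <- txt3[!grepl("^wavelength", txt3)]
  hdr3 <- withr::local_tempfile(fileext = ".hdr")
  writeLines(txt3, hdr3)
  expect_error(read_envi(hdr3, dat), "wavelength")
})

test_that("reflectance correction satisfies the two-point identities", {
  d <- c(4, 5, 6)
  dark <- array(100, d); white <- array(3000, d)
  grid <- tiny_grid(6)
  expect_equal(
    correct_reflectance(raw_cube(white, grid), dark, white)$data,
    array(1, d))
  expect_equal(
    correct_reflectance(raw_cube(dark, grid), dark, white)$data,
    array(0, d))
  expect_equal(
    correct_reflectance(raw_cube((dark + white) / 2, grid), dark,
                        white)$data,
    array(0.5, d))
})

test_that("correction is invariant to a common positive gain", {
  cube <- tiny_cube(3, 3, 4, seed = 9)
  dark <- array(120, dim(cube$data))
  white <- array(3500, dim(cube$data))
  r1 <- correct_reflectance(cube, dark, white)
  cube2 <- raw_cube(cube$data * 2.5, cube$wavelengths)
  r2 <- correct_reflectance(cube2, dark * 2.5, white * 2.5)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("degenerate calibration pixels are masked out, not clamped", {
  d <- c(3, 3, 2)
  dark <- array(100, d)
  white <- array(3000, d)
  white[1, 1, 1] <- 50       # white below dark in one band
  raw <- raw_cube(array(500, d), tiny_grid(2))
  r <- correct_reflectance(raw, dark, white)
  expect_false(r$valid_mask[1, 1])
  expect_true(all(r$valid_mask[-1]))
  expect_true(all(is.na(r$data[1, 1, ])))
  expect_true(all(is.finite(r$data[, , ][rep(r$valid_mask, 2)])))

  expect_error(correct_reflectance(raw, white, dark),
               "degenerate calibration")
})

test_that("segmentation rejects uniform images and filters small components", {
  d <- c(20, 20, 3)
  uni <- reflectance_cube(array(0.5, d), tiny_grid(3))
  expect_error(segment_sample(uni), "no sample detected")

  img <- array(0.1, d)
  img[5:14, 5:14, ] <- 0.8       # 100-px object
  img[18, 18, ] <- 0.8           # 1-px speck
  cube <- reflectance_cube(img, tiny_grid(3))
  m1 <- segment_sample(cube, min_size = 1)
  m2 <- segment_sample(cube, min_size = 10)
  m3 <- segment_sample(cube, min_size = 50)
  expect_gte(sum(m1), sum(m2))
  expect_gte(sum(m2), sum(m3))
  expect_equal(sum(m3), 100)
  expect_false(m2[18, 18])
})

test_that("mean_spectrum is the per-band arithmetic mean over the mask", {
  d <- c(2, 1, 2)
  arr <- array(c(1, 3, 3, 5), d)  # pixel (1,1) = [1,3], pixel (2,1) = [3,5]
  cube <- reflectance_cube(arr, tiny_grid(2))
  mask <- matrix(TRUE, 2, 1)
  expect_equal(mean_spectrum(cube, mask), c(2, 4))

  single <- matrix(c(TRUE, FALSE), 2, 1)
  expect_equal(mean_spectrum(cube, single), c(1, 3))

  expect_error(mean_spectrum(cube, matrix(FALSE, 2, 1)), "empty")
})

test_that("band trimming keeps the closed interval and is idempotent", {
  s <- spectra_set(matrix(1, 2, 5), c(100, 110, 120, 130, 140))
  t1 <- trim_bands(s, 105, 135)
  expect_equal(t1$wavelengths, c(110, 120, 130))

  full <- trim_bands(s, 100, 140)
  expect_equal(full$matrix, s$matrix)

  expect_identical(trim_bands(t1, 105, 135)$wavelengths, t1$wavelengths)
  expect_error(trim_bands(s, 150, 141), "lo_nm must be")
  expect_error(trim_bands(s, 141, 142), "no channel")
})

test_that("mean_spectrum commutes with band trimming", {
  cube <- tiny_cube(4, 4, 8, seed = 11)
  refl <- reflectance_cube(cube$data / 4000, cube$wavelengths)
  mask <- matrix(TRUE, 4, 4)
  m_then_t <- trim_bands(
    spectra_set(matrix(mean_spectrum(refl, mask), 1), refl$wavelengths),
    1020, 1090)
  sub <- refl$wavelengths >= 1020 & refl$wavelengths <= 1090
  t_then_m <- mean_spectrum(
    reflectance_cube(refl$data[, , sub], refl$wavelengths[sub]), mask)
  expect_equal(as.numeric(m_then_t$matrix), t_then_m, tolerance = 1e-12)
})
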