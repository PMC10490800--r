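test_that("SNV standardizes each spectrum to mean 0, sd 1 (n-1)", {
  s <- spectra_set(matrix(c(1, 2, 3), 1), tiny_grid(3))
  pp <- preprocess_fit("SNV", s)
  expect_equal(as.numeric(preprocess_apply(pp, s)$matrix), c(-1, 0, 1))

  r <- random_spectra(20, 30)
  out <- preprocess_apply(preprocess_fit("SNV", r), r)$matrix
  expect_lt(max(abs(rowMeans(out))), 1e-10)
  expect_lt(max(abs(apply(out, 1, stats::sd) - 1)), 1e-10)

  const <- spectra_set(matrix(2, 1, 5), tiny_grid(5))
  expect_error(preprocess_apply(preprocess_fit("SNV", r2 <- random_spectra(3, 5)),
                                const),
               "constant spectrum")
})

test_that("MSC inverts affine scatter distortions exactly", {
  r <- as.numeric(random_spectra(1, 15, seed = 4)$matrix)
  train <- spectra_set(rbind(r, r), tiny_grid(15), c("a", "b"))
  pp <- preprocess_fit("MSC", train)
  expect_equal(pp$state$reference, r, ignore_attr = TRUE)

  x <- spectra_set(matrix(2 * r + 1, 1), tiny_grid(15))
  expect_equal(as.numeric(preprocess_apply(pp, x)$matrix), r,
               ignore_attr = TRUE, tolerance = 1e-12)

  # a training population of affine distortions of r is mapped back onto r:
  # the corrected training mean equals the reference
  gains <- c(0.8, 1.1, 1.3, 0.95); offs <- c(0.1, -0.2, 0.05, 0)
  mat <- t(vapply(1:4, function(i) gains[i] * r + offs[i], numeric(15)))
  tr2 <- spectra_set(mat, tiny_grid(15))
  pp2 <- preprocess_fit("MSC", tr2)
  corr <- preprocess_apply(pp2, tr2)$matrix
  expect_lt(max(abs(colMeans(corr) - pp2$state$reference)), 1e-8)
})

test_that("finite-difference derivatives are exact on polynomials", {
  w <- tiny_grid(10, 0, 9)  # unit spacing
  a <- 0.7
  quad <- spectra_set(matrix(a * w^2, 1), w)
  sd_out <- preprocess_apply(preprocess_fit("SD", quad), quad)
  expect_equal(as.numeric(sd_out$matrix), rep(2 * a, 8), tolerance = 1e-10)
  expect_equal(sd_out$wavelengths, w[2:9])

  lin <- spectra_set(matrix(3 * w + 1, 1), w)
  fd_out <- preprocess_apply(preprocess_fit("FD", lin), lin)
  expect_equal(as.numeric(fd_out$matrix), rep(3, 9), tolerance = 1e-10)
  expect_equal(fd_out$wavelengths, (w[-1] + w[-10]) / 2)
})

test_that("FD and SD are linear operators", {
  x <- random_spectra(1, 20, seed = 5)
  y <- random_spectra(1, 20, seed = 6)
  for (m in c("FD", "SD")) {
    pp <- preprocess_fit(m, x)
    lhs <- preprocess_apply(pp,
      spectra_set(2 * x$matrix + 3 * y$matrix, x$wavelengths))$matrix
    rhs <- 2 * preprocess_apply(pp, x)$matrix +
      3 * preprocess_apply(pp, y)$matrix
    expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("SG second derivative is exact on cubics and matches sgolay", {
  w <- tiny_grid(20, 0, 38)  # spacing 2
  x <- 0.3 * w^3 - 2 * w^2 + w - 5
  s <- spectra_set(matrix(x, 1), w)
  pp <- preprocess_fit("SG", s, sg_window = 9, sg_degree = 3, sg_deriv = 2)
  out <- preprocess_apply(pp, s)
  analytic <- 6 * 0.3 * out$wavelengths - 4
  expect_equal(as.numeric(out$matrix), analytic, tolerance = 1e-8)
  expect_length(out$wavelengths, 20 - 8)

  skip_if_not_installed("signal")
  # independent coefficient check against the signal package
  # sgolay's filter rows already include the factorial scaling
  cw <- pellspec:::sg_weights(9, 3, 2)
  ref <- signal::sgolay(p = 3, n = 9, m = 2)[5, ]
  expect_equal(as.numeric(cw), as.numeric(ref), tolerance = 1e-10)
})

test_that("SG derivative suppresses noise relative to the plain SD", {
  withr::with_seed(77, {
    noise <- matrix(rnorm(1000 * 40), 1000)
  })
  s <- spectra_set(noise + 1, tiny_grid(40, 0, 39))
  v_sd <- apply(preprocess_apply(preprocess_fit("SD", s), s)$matrix, 2,
                stats::var)
  v_sg <- apply(preprocess_apply(preprocess_fit("SG", s), s)$matrix, 2,
                stats::var)
  expect_lt(mean(v_sg), mean(v_sd))
})

test_that("MC and MMN use training statistics and expose them", {
  tr <- random_spectra(6, 8, seed = 7)
  mc <- preprocess_fit("MC", tr)
  expect_equal(mc$state$means, colMeans(tr$matrix))
  out <- preprocess_apply(mc, tr)$matrix
  expect_lt(max(abs(colMeans(out))), 1e-12)
  # idempotent on already-centered data
  centered <- spectra_set(out, tr$wavelengths, tr$sample_ids)
  mc2 <- preprocess_fit("MC", centered)
  expect_equal(preprocess_apply(mc2, centered)$matrix, out,
               tolerance = 1e-12)

  mm_tr <- spectra_set(cbind(c(2, 4, 6), c(1, 2, 4)), c(1000, 1010))
  mm <- preprocess_fit("MMN", mm_tr)
  out2 <- preprocess_apply(mm, mm_tr)$matrix
  expect_equal(out2[, 1], c(0, 0.5, 1), ignore_attr = TRUE)

  # out-of-range apply values are not clipped
  test <- spectra_set(cbind(8, 5), c(1000, 1010))
  expect_gt(preprocess_apply(mm, test)$matrix[1, 1], 1)

  one <- spectra_set(matrix(1:3, 1), tiny_grid(3))
  expect_error(preprocess_fit("MMN", one), "distinct values")
})

test_that("SNV fit stores no state and grids are enforced", {
  tr <- random_spectra(4, 6)
  snv <- preprocess_fit("SNV", tr)
  expect_length(snv$state, 0)

  other <- random_spectra(4, 7)
  expect_error(preprocess_apply(snv, other), "grid")
  expect_error(preprocess_fit("SG", tr, sg_window = 8), "odd")
  expect_error(preprocess_fit("SG", tr, sg_window = 3, sg_degree = 3),
               "greater than")
  expect_error(preprocess_fit("XYZ", tr), "unknown preprocessing")
})

test_that("stateful transforms are not idempotent, unlike MC on centered data", {
  r <- random_spectra(5, 30, seed = 12)
  mm <- preprocess_fit("MMN", r)
  once <- preprocess_apply(mm, r)
  twice <- preprocess_apply(mm, once)
  expect_false(isTRUE(all.equal(twice$matrix, once$matrix)))

  sd1 <- preprocess_apply(preprocess_fit("SD", r), r)
  sd2 <- preprocess_apply(preprocess_fit("SD", sd1), sd1)
  expect_false(ncol(sd2$matrix) == ncol(sd1$matrix))
})
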