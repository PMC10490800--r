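test_that("held-out coverage matches the binomial expectation", {
  st <- study_set(seed = 101, n = 60)
  rep <- mccv_residuals(st$trimmed, st$refs, n_iterations = 1000,
                        seed = 21)
  # expected appearances = 0.25 * 1000 = 250; concentration keeps every
  # sample well above 150
  expect_true(all(rep$n_appearances >= 150))
  expect_equal(mean(rep$n_appearances), 250, tolerance = 0.1)
  expect_true(all(is.finite(rep$mean)) && all(is.finite(rep$std)))
})

test_that("a planted y-shift dominates the MEAN axis and is flagged", {
  st <- study_set(seed = 102, n = 60)
  refs <- st$refs
  refs$moisture[7] <- refs$moisture[7] + 8
  rep <- mccv_residuals(st$trimmed, refs, n_iterations = 300, seed = 22)
  expect_equal(rep$sample_id[which.max(abs(rep$mean))],
               st$refs$sample_id[7])
  expect_true(st$refs$sample_id[7] %in% flag_outliers(rep))
})

test_that("MCCV reports are deterministic and order-invariant", {
  st <- study_set(seed = 103, n = 40)
  r1 <- mccv_residuals(st$trimmed, st$refs, n_iterations = 150, seed = 5)
  r2 <- mccv_residuals(st$trimmed, st$refs, n_iterations = 150, seed = 5)
  expect_identical(r1, r2)

  perm <- withr::with_seed(9, sample(40))
  shuffled <- spectra_set(st$trimmed$matrix[perm, ],
                          st$trimmed$wavelengths,
                          st$trimmed$sample_ids[perm])
  r3 <- mccv_residuals(shuffled, st$refs, n_iterations = 150, seed = 5,
                       pls_components = attr(r1, "pls_components"))
  # same population statistics up to relabeling (different draw sequences)
  expect_equal(sort(r3$sample_id), sort(r1$sample_id))
  expect_equal(mean(r3$std), mean(r1$std), tolerance = 0.25)
})

test_that("flag rule arithmetic: identical points, gross deviants, monotonicity", {
  flat <- structure(data.frame(sample_id = letters[1:10],
                               mean = rep(0.2, 10), std = rep(0.1, 10),
                               n_appearances = 50L),
                    class = c("outlier_report", "data.frame"))
  expect_length(suppressWarnings(flag_outliers(flat)), 0)
  half <- flat
  half$mean <- seq(-0.3, 0.3, length.out = 10)   # only the STD axis is flat
  expect_warning(flag_outliers(half), "MAD is zero")

  one_far <- flat
  one_far$std <- seq(0.05, 0.2, length.out = 10)    # non-degenerate axis
  one_far$mean[1:9] <- seq(-0.4, 0.4, length.out = 9)
  one_far$mean[10] <- stats::median(one_far$mean[1:9]) +
    10 * stats::mad(one_far$mean[1:9])
  expect_true("j" %in% flag_outliers(one_far))

  st <- study_set(seed = 104, n = 50)
  refs <- st$refs
  refs$moisture[c(3, 9)] <- refs$moisture[c(3, 9)] + 8
  rep <- mccv_residuals(st$trimmed, refs, n_iterations = 200, seed = 6)
  f3 <- flag_outliers(rep, z_threshold = 3)
  f5 <- flag_outliers(rep, z_threshold = 5)
  f9 <- flag_outliers(rep, z_threshold = 9)
  expect_true(all(f5 %in% f3))
  expect_true(all(f9 %in% f5))
})

test_that("MCCV validates its configuration", {
  st <- study_set(seed = 105, n = 20)
  expect_error(mccv_residuals(st$trimmed, st$refs, train_fraction = 1),
               "train_fraction")
  expect_error(mccv_residuals(st$trimmed, st$refs, n_iterations = 50),
               "n_iterations")
  expect_error(mccv_residuals(st$trimmed, st$refs, n_iterations = 100,
                              pls_components = 15),
               "smaller than the calibration")
})

test_that("rejecting planted outliers improves the refitted model", {
  st <- study_set(seed = 106, n = 100)
  refs <- st$refs
  bad <- c(11, 52, 90)
  refs$moisture[bad] <- refs$moisture[bad] + 8
  rep <- mccv_residuals(st$trimmed, refs, n_iterations = 300, seed = 7)
  fl <- flag_outliers(rep)
  expect_true(all(st$refs$sample_id[bad] %in% fl))

  sp <- split_samples(st$trimmed, 0.25, seed = 8)
  y <- refs$moisture
  fit_eval <- function(keep) {
    tr <- intersect(sp$train, keep); te <- intersect(sp$test, keep)
    nc <- select_nc(st$trimmed$matrix[tr, ], y[tr], max_nc = 8,
                    seed = 9)$nc
    m <- fit_plsr(st$trimmed$matrix[tr, ], y[tr], nc)
    evaluate(y[te], predict(m, st$trimmed$matrix[te, ]), "test")$r2
  }
  r2_all <- fit_eval(seq_len(100))
  r2_clean <- fit_eval(which(!(refs$sample_id %in% fl)))
  expect_gt(r2_clean, r2_all)
})
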