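# shared fixtures, all generated in code

tiny_grid <- function(p = 12L, from = 1000, to = 1110) {
  seq(from, to, length.out = p)
}

tiny_cube <- function(rows = 4L, cols = 5L, bands = 6L, seed = 1L) {
  withr::with_seed(seed, {
    raw_cube(array(runif(rows * cols * bands, 100, 4000),
                   c(rows, cols, bands)),
             tiny_grid(bands))
  })
}

random_spectra <- function(n = 8L, p = 12L, seed = 1L) {
  withr::with_seed(seed, {
    spectra_set(matrix(rnorm(n * p, 0.5, 0.1), n), tiny_grid(p))
  })
}

# default-condition synthetic study set, trimmed to the working range
study_set <- function(seed = 20230901L, n = 144L) {
  refs <- generate_reference_values(n, seed = seed)
  gen <- generate_spectra(refs, default_grid(), sim_config(seed = seed))
  list(refs = refs, spectra = gen$spectra, truth = gen$truth,
       trimmed = trim_bands(gen$spectra))
}

# independent SPA oracle: literal restatement of the projection recursion -
# at every step, project ALL remaining columns orthogonal to the last
# selected one and take the argmax norm
spa_brute <- function(X, k0, N) {
  P <- X
  chain <- k0
  remaining <- setdiff(seq_len(ncol(X)), k0)
  while (length(chain) < N) {
    last <- P[, chain[length(chain)]]
    for (j in remaining)
      P[, j] <- P[, j] - last * sum(last * P[, j]) / sum(last^2)
    norms <- vapply(remaining, function(j) sqrt(sum(P[, j]^2)), numeric(1))
    if (max(norms) < 1e-12) break
    nxt <- remaining[which.max(norms)]
    chain <- c(chain, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  chain
}
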