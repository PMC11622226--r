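# Fixtures are built in code at test time; nothing binary is stored.

# A random cube written to disk; values are returned float32-rounded so
# comparisons against read-back data can be exact.
rand_cube <- function(n_spectra, n_peaks, seed = 1L, scale = 10) {
  set.seed(seed)
  x <- float32_round(matrix(rnorm(n_spectra * n_peaks, sd = scale),
                            n_spectra, n_peaks))
  path <- tempfile(fileext = ".bin")
  cube <- write_datacube(x, path)
  list(cube = cube, values = x, path = path)
}

# Dense PCA oracle, independent of the package's own SVD path: centred
# crossproduct eigendecomposition.
oracle_pca_eigen <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  eig <- eigen(crossprod(xc), symmetric = TRUE)
  list(singular_values = sqrt(pmax(eig$values, 0)),
       components = t(eig$vectors),
       explained_variance = pmax(eig$values, 0) / (nrow(x) - 1))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
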