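test_that("default batch size is 19x the peak count, clipped to the cube", {
  expect_equal(default_batch_size(310, 262144), 5890L)
  expect_equal(default_batch_size(199, 35000), 3781L)
  expect_equal(default_batch_size(33, 100), 100L)     # clipped to n_spectra
  expect_equal(default_batch_size(50, 60), 60L)
  expect_error(default_batch_size(0, 10))
})

test_that("incremental mean/variance agrees with one-pass statistics", {
  s <- new_fit_state(1, 1)
  s <- update_mean_var(s, matrix(c(1, 3), 2, 1))
  s <- update_mean_var(s, matrix(c(5, 7), 2, 1))
  expect_equal(s$n_seen, 4L)
  expect_equal(s$mean, 4)
  expect_equal(s$m2, 20)       # sum((x - 4)^2) over {1,3,5,7}

  # initialisation from empty state
  set.seed(31)
  b <- matrix(rnorm(12), 4, 3)
  s0 <- update_mean_var(new_fit_state(3), b)
  expect_equal(s0$mean, colMeans(b))
  expect_equal(s0$m2, colSums(sweep(b, 2, colMeans(b))^2))

  # two identical batches: correction term vanishes
  s1 <- update_mean_var(s0, b)
  expect_equal(s1$mean, colMeans(b))
  expect_equal(s1$m2, 2 * s0$m2)

  # property: random splits match the one-pass oracle
  set.seed(77)
  for (rep in 1:5) {
    x <- matrix(rnorm(60 * 4, mean = 5, sd = 3), 60, 4)
    cuts <- sort(sample(2:59, 3))
    st <- new_fit_state(4)
    start <- 1
    for (end in c(cuts, 60)) {
      st <- update_mean_var(st, x[start:end, , drop = FALSE])
      start <- end + 1
    }
    expect_equal(st$mean, colMeans(x), tolerance = 1e-12)
    expect_equal(st$m2, colSums(sweep(x, 2, colMeans(x))^2),
                 tolerance = 1e-10)
  }
  expect_error(update_mean_var(new_fit_state(2), matrix(c(1, Inf), 1, 2)),
               "finite")
})

test_that("a single partial_fit reproduces the hand-computed SVD", {
  x <- matrix(c(2, 0, -2, 0, 0, 1, 0, -1), ncol = 2, byrow = TRUE)
  s <- partial_fit(new_fit_state(2, k = 2), x)
  expect_equal(s$singular_values, c(sqrt(8), sqrt(2)))
  expect_equal(s$components, diag(2))     # axis-aligned, signs positive
  fin <- finalize_explained_variance(s)
  expect_equal(fin$explained_variance, c(8 / 3, 2 / 3))
  expect_equal(fin$explained_variance_ratio, c(0.8, 0.2))
})

test_that("first batch smaller than k is rejected", {
  expect_error(partial_fit(new_fit_state(4, k = 4), matrix(rnorm(8), 2, 4)),
               "first batch")
})

test_that("batched updates track the dense SVD oracle", {
  set.seed(11)
  x <- matrix(rnorm(200 * 10), 200, 10)
  st <- new_fit_state(10, k = 10)
  for (i in 1:4) st <- partial_fit(st, x[((i - 1) * 50 + 1):(i * 50), ])
  oracle <- oracle_pca_eigen(x)
  expect_rel_equal(st$singular_values, oracle$singular_values, 1e-3)
  ang <- principal_angles(st$components[1:5, ],
                          t(svd(sweep(x, 2, colMeans(x)))$v)[1:5, ])
  expect_lt(max(ang), 1e-3)
})

test_that("loadings stay orthonormal and ordered through a fit", {
  rc <- rand_cube(400, 12, seed = 21)
  m <- ipca_fit(rc$cube, batch_size = 90)
  G <- m$components %*% t(m$components)
  expect_lt(max(abs(G - diag(m$k))), 1e-4)
  expect_true(all(diff(m$singular_values) <= 1e-9))
  expect_equal(m$n_seen, 400L)
  expect_rel_equal(m$mean, colMeans(rc$values), 1e-5)
})

test_that("single-batch fit is exact PCA", {
  rc <- rand_cube(150, 8, seed = 13)
  inc <- ipca_fit(rc$cube, batch_size = 150)
  ex <- exact_pca(rc$cube)
  expect_rel_equal(inc$singular_values, ex$singular_values, 1e-5)
  expect_equal(inc$components, ex$components, tolerance = 1e-5)
  expect_equal(inc$explained_variance_ratio, ex$explained_variance_ratio,
               tolerance = 1e-5)
})

test_that("batch-size choice does not move the singular values", {
  rc <- rand_cube(800, 10, seed = 17)
  fits <- lapply(c(10L, 50L, 190L, 800L),
                 function(d) ipca_fit(rc$cube, batch_size = d))
  ref <- fits[[length(fits)]]$singular_values
  for (f in fits)
    expect_rel_equal(f$singular_values, ref, 1e-3)
})

test_that("variance is conserved at k = n_peaks", {
  rc <- rand_cube(300, 9, seed = 23)
  m <- ipca_fit(rc$cube, batch_size = 70)
  expect_equal(sum(m$explained_variance_ratio), 1, tolerance = 1e-3)
  # against a one-pass total-variance oracle
  expect_rel_equal(sum(m$explained_variance),
                   sum(apply(rc$values, 2, var)), 1e-3)
})

test_that("zero-variance cubes give zero singular values and ratios", {
  p <- tempfile(fileext = ".bin")
  cube <- write_datacube(matrix(5, 40, 4), p)
  m <- ipca_fit(cube, batch_size = 10)
  expect_true(all(m$singular_values < 1e-6))
  expect_equal(m$explained_variance_ratio, rep(0, 4))
})

test_that("rank-1 noiseless cubes put all variance on PC1", {
  u <- seq_len(50) / 50
  v <- c(3, 1, -2, 0.5)
  p <- tempfile(fileext = ".bin")
  cube <- write_datacube(float32_round(outer(u, v)), p)
  m <- ipca_fit(cube, batch_size = 20)
  expect_equal(m$explained_variance_ratio[1], 1, tolerance = 1e-5)
})

test_that("first batch is enlarged when batch_size < k", {
  rc <- rand_cube(100, 20, seed = 3)
  m <- ipca_fit(rc$cube, k = 20, batch_size = 5)
  expect_equal(m$n_seen, 100L)
  ex <- exact_pca(rc$cube)
  expect_rel_equal(m$singular_values[1:5], ex$singular_values[1:5], 1e-3)
})

test_that("explained variance needs at least two rows", {
  s <- update_mean_var(new_fit_state(2), matrix(1:2, 1, 2))
  expect_error(finalize_explained_variance(s), "at least 2")
})
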