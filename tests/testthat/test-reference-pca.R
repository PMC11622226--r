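test_that("exact_pca matches the covariance eigendecomposition oracle", {
  rc <- rand_cube(120, 7, seed = 61)
  m <- exact_pca(rc$cube)
  oracle <- oracle_pca_eigen(rc$values)
  expect_rel_equal(m$explained_variance, oracle$explained_variance, 1e-4)
  # also against prcomp's sdev
  pr <- prcomp(rc$values, center = TRUE, scale. = FALSE)
  expect_rel_equal(m$explained_variance, pr$sdev^2, 1e-6)
  expect_error(exact_pca(rc$cube, k = 10), "exceeds")
})

test_that("exact_pca on rank-1 data yields ratio 1", {
  x <- outer(rnorm(40), c(2, -1, 0.5))
  m <- exact_pca(x, k = 1)
  expect_equal(m$explained_variance_ratio, 1, tolerance = 1e-10)
})

test_that("subsampled_pca defaults and degenerate fraction behave", {
  expect_equal(formals(subsampled_pca)$fraction, 0.065)
  rc <- rand_cube(200, 6, seed = 67)
  full <- subsampled_pca(rc$cube, fraction = 1.0)
  ex <- exact_pca(rc$cube)
  expect_equal(full$singular_values, ex$singular_values)
  expect_equal(full$components, ex$components)
})

test_that("subsampled_pca is seed-deterministic, seeds differ only mildly", {
  sp <- synthetic_spec(4000, 20, rank = 3, seed = 5)
  g <- generate_datacube(sp, tempfile())
  a <- subsampled_pca(g$cube, seed = 1L)
  b <- subsampled_pca(g$cube, seed = 1L)
  expect_identical(a$components, b$components)
  c_ <- subsampled_pca(g$cube, seed = 2L)
  expect_false(identical(a$components, c_$components))
  aligned <- align_signs(a$components[1, , drop = FALSE],
                         c_$components[1, , drop = FALSE])
  r2 <- cor(a$components[1, ], aligned[1, ])^2
  expect_gt(r2, 0.9)     # high-SNR cube: top component robust to the sample
})

test_that("align_signs makes every component dot product nonnegative", {
  set.seed(71)
  ref <- matrix(rnorm(40), 5, 8)
  expect_identical(align_signs(ref, ref), ref)
  expect_equal(align_signs(ref, -ref), ref)
  other <- matrix(rnorm(40), 5, 8)
  out <- align_signs(ref, other)
  expect_true(all(rowSums(ref * out) >= 0))
  expect_error(align_signs(ref, other[, 1:4]), "shape")
})

test_that("loading_metrics: exact match, shifts, perturbations, symmetry", {
  set.seed(73)
  a <- matrix(rnorm(3 * 50), 3, 50)
  same <- loading_metrics(a, a)
  expect_equal(same$per_component$mse, rep(0, 3))
  expect_equal(same$per_component$r2, rep(1, 3))

  shifted <- loading_metrics(a, a + 0.4)
  expect_equal(shifted$per_component$r2, rep(1, 3), tolerance = 1e-12)
  expect_equal(shifted$per_component$mse, rep(0.16, 3), tolerance = 1e-12)

  eps <- 1e-3
  noise <- matrix(rnorm(3 * 50), 3, 50)
  pert <- loading_metrics(a, a + eps * noise)
  expect_equal(pert$per_component$mse,
               eps^2 * rowMeans(noise^2), tolerance = 1e-12)

  # symmetry in the arguments
  b <- a + eps * noise
  expect_equal(loading_metrics(a, b)$per_component,
               loading_metrics(b, a)$per_component)

  # zero-variance vector: r2 missing, not 0
  z <- a; z[2, ] <- 7
  expect_true(is.na(loading_metrics(a, z)$per_component$r2[2]))
})

test_that("grouped r2 covers the 1-10 / 11-20 / 21-30 ranges", {
  set.seed(79)
  a <- matrix(rnorm(25 * 30), 25, 30)
  rep_ <- loading_metrics(a, a + 1e-4 * matrix(rnorm(25 * 30), 25, 30))
  expect_setequal(rep_$grouped$range, c("1-10", "11-20", "21-30"))
  expect_true(all(rep_$grouped$mean_r2 >= 0 & rep_$grouped$mean_r2 <= 1))
})

test_that("score differences in percent of range behave as specified", {
  set.seed(83)
  s <- matrix(rnorm(100 * 3), 100, 3)
  same <- score_difference_percent(s, s, 2)
  expect_equal(same$percent, rep(0, 100))

  rng <- max(s[, 1]) - min(s[, 1])
  off <- s; off[, 1] <- off[, 1] + 0.01 * rng
  d <- score_difference_percent(s, off, 1)
  expect_equal(d$percent, rep(-1, 100), tolerance = 1e-9)
  expect_equal(c(d$min_pct, d$max_pct), c(-1, -1), tolerance = 1e-9)

  # antisymmetry under argument swap (same reference range here)
  a <- s; a[, 1] <- a[, 1] + rnorm(100, sd = 0.01 * rng)
  expect_equal(score_difference_percent(s, a, 1)$percent,
               -score_difference_percent(a, s, 1)$percent, tolerance = 0.05)

  expect_error(score_difference_percent(s, matrix(0, 100, 3), 4), "range")
  z <- s; z[, 2] <- 1
  expect_error(score_difference_percent(z, s, 2), "zero range")
})

test_that("principal angles are zero within, pi/2 across, subspaces", {
  e <- diag(4)
  expect_equal(principal_angles(e[1:2, ], e[1:2, ]), c(0, 0))
  expect_equal(principal_angles(e[1, , drop = FALSE],
                                e[2, , drop = FALSE]), pi / 2)
  # rotation within the span leaves angles at ~0
  set.seed(89)
  A <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  B <- t(R %*% t(A))
  expect_lt(max(principal_angles(t(A), t(B))), 1e-8)
  expect_error(principal_angles(matrix(1, 2, 4), e[1:2, ]), "orthonormal")
})

test_that("subsampled loadings are consistently worse than incremental", {
  # planted rank-3 cubes, moderate noise; averaged over 5 seeds the
  # subsample-vs-exact MSE must strictly exceed the incremental-vs-exact MSE
  mse_sub <- mse_inc <- numeric(5)
  for (i in 1:5) {
    sp <- synthetic_spec(6000, 30, rank = 3, seed = 100 + i,
                         lambda0 = 10 * 50 * (sqrt(6000) + sqrt(30)))
    g <- generate_datacube(sp, tempfile())
    # metrics over the planted components only: beyond the planted rank the
    # directions are noise-degenerate and the comparison is uninformative
    ex <- exact_pca(g$cube, k = 3)
    inc <- ipca_fit(g$cube, k = 3, batch_size = 570)
    sub <- subsampled_pca(g$cube, seed = i, k = 3)
    m_inc <- loading_metrics(ex$components,
                             align_signs(ex$components, inc$components))
    m_sub <- loading_metrics(ex$components,
                             align_signs(ex$components, sub$components))
    mse_inc[i] <- mean(m_inc$per_component$mse)
    mse_sub[i] <- mean(m_sub$per_component$mse)
  }
  expect_gt(mean(mse_sub), mean(mse_inc))
})
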