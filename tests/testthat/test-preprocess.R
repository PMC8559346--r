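test_that("z-score fit uses the population convention and flags constants", {
  zs <- zscore_fit(data.frame(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(zs$means), c(2, 5))
  expect_equal(unname(zs$stds[1]), sqrt(2 / 3), tolerance = 1e-12)
  expect_true(zs$zero_var[["b"]])
  expect_equal(unname(zs$stds[2]), 1)
  Z <- zscore_transform(data.frame(a = c(1, 2, 3), b = c(5, 5, 5)), zs)
  expect_equal(unname(Z[, 2]), c(0, 0, 0))
  expect_error(zscore_fit(data.frame(a = 1)), "2 rows")
})

test_that("transformed training data has mean 0 and sd 1 per column", {
  X <- withr::with_seed(3, matrix(rnorm(200 * 6, 5, 3), 200, 6))
  colnames(X) <- paste0("f", 1:6)
  zs <- zscore_fit(X)
  Z <- zscore_transform(X, zs)
  expect_equal(unname(colMeans(Z)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(sqrt(colMeans(Z^2))), rep(1, 6), tolerance = 1e-9)
})

test_that("PCA retains the smallest basis reaching the variance target", {
  # data confined to a 3-D subspace of 10-D
  withr::with_seed(5, {
    B <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:3]
    X <- matrix(rnorm(300 * 3), 300, 3) %*% t(B)
  })
  m <- pca_fit(X, 0.999)
  expect_equal(m$n_retained, 3)

  Xf <- withr::with_seed(6, matrix(rnorm(50 * 8), 50, 8))
  expect_equal(pca_fit(Xf, 1.0)$n_retained, 8)
  expect_error(pca_fit(Xf, 1.5), "variance_threshold")
  expect_error(pca_fit(Xf, 0), "variance_threshold")
})

test_that("component variances match an independent eigendecomposition", {
  X <- withr::with_seed(9, matrix(rnorm(200 * 150), 200, 150))
  colnames(X) <- paste0("f", 1:150)
  zs <- zscore_fit(X)
  Z <- zscore_transform(X, zs)
  m <- pca_fit(Z, 0.999)
  proj <- as.matrix(transform_features(X, zs, m))
  ev <- sort(eigen(stats::cov(Z), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  pv <- apply(proj, 2, stats::var)
  expect_equal(unname(pv), ev[seq_len(m$n_retained)], tolerance = 1e-8)
  # orthonormal basis
  G <- crossprod(m$rotation)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  # cumulative retained variance reaches the target
  expect_gte(sum(m$explained_variance_ratio[seq_len(m$n_retained)]), 0.999)
})

test_that("projection satisfies the Parseval decomposition", {
  X <- withr::with_seed(11, matrix(rnorm(120 * 20), 120, 20))
  colnames(X) <- paste0("f", 1:20)
  zs <- zscore_fit(X)
  Z <- zscore_transform(X, zs)
  m <- pca_fit(Z, 0.9)  # deliberately lossy
  proj <- as.matrix(transform_features(X, zs, m))
  Zc <- sweep(Z, 2, m$center)
  total_ss <- sum(Zc^2)
  recon <- proj %*% t(m$rotation)
  resid_ss <- sum((Zc - recon)^2)
  n <- nrow(Z)
  # residual sum of squares equals the total variance not retained
  expect_equal(resid_ss / (n - 1),
               sum(eigen(stats::cov(Z), only.values = TRUE)$values) -
                 sum(apply(proj, 2, stats::var)),
               tolerance = 1e-6)
  # zero vector projects to zero
  z0 <- matrix(zs$means, 1)  # standardizes to the zero vector
  colnames(z0) <- paste0("f", 1:20)
  p0 <- as.matrix(transform_features(z0, zs, m))
  expect_equal(unname(p0[1, ]), -unname(as.vector(m$center %*% m$rotation)),
               tolerance = 1e-10)
  # duplicated rows project identically
  dup <- X[c(1, 1), ]
  pd <- as.matrix(transform_features(dup, zs, m))
  expect_equal(pd[1, ], pd[2, ])
})

test_that("transform is affine on the standardized space", {
  X <- withr::with_seed(13, matrix(rnorm(60 * 10), 60, 10))
  colnames(X) <- paste0("f", 1:10)
  zs <- zscore_fit(X)
  m <- pca_fit(zscore_transform(X, zs), 0.999)
  x <- X[1, , drop = FALSE]; y <- X[2, , drop = FALSE]
  for (al in c(0.25, 0.5, 0.9)) {
    mix <- al * x + (1 - al) * y
    colnames(mix) <- colnames(X)
    lhs <- as.matrix(transform_features(mix, zs, m))
    rhs <- al * as.matrix(transform_features(x, zs, m)) +
      (1 - al) * as.matrix(transform_features(y, zs, m))
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("width mismatches are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  zs <- zscore_fit(X)
  expect_error(zscore_transform(matrix(0, 2, 3), zs), "feature count")
})
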