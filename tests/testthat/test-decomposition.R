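test_that("whitening yields identity row covariance and keeps top directions", {
  x <- gaussian_matrix(100, 20, seed = 1)
  w <- whiten(x, 5)
  expect_equal(dim(w$y), c(5L, 20L))
  expect_equal(unname(tcrossprod(w$y) / ncol(x)), diag(5), tolerance = 1e-8)
  # transform reproduces y from the centred input
  expect_equal(unname(w$transform %*% (x - w$center)), unname(w$y), tolerance = 1e-8)
  # rank-1 input, k = 1: one whitened row with unit variance
  s <- rnorm(30)
  a <- rnorm(10)
  r1 <- labeled_matrix(s %*% t(a), 30, 10)
  w1 <- whiten(r1, 1)
  expect_equal(mean(w1$y^2), 1, tolerance = 1e-8)
})

test_that("whitening refuses k beyond the effective rank, reporting it", {
  set.seed(2)
  s <- matrix(rnorm(40), 20, 2)
  a <- matrix(rnorm(12), 2, 6)
  x <- labeled_matrix(s %*% a, 20, 6)
  expect_error(whiten(x, 3), "rank.*2")
  expect_error(whiten(x, 0), "positive")
  expect_error(whiten(x, 7), "min\\(dim")
})

test_that("symmetric FastICA separates dense Laplace signatures from a noise-free mixture", {
  mix <- dense_mixture(2000, 100, k = 2, seed = 1, scale = 1)
  d <- decompose_expression(mix$x, method = "ICA", k = 2, seed = 1)
  m <- match_components(d$signatures, mix$s)
  expect_true(all(m$abs_r >= 0.95))
  expect_true(d$converged)
})

test_that("recovered signatures are standardized, sign-oriented and pairwise decorrelated", {
  mix <- dense_mixture(2000, 80, k = 3, seed = 4, scale = 2)
  d <- decompose_expression(mix$x, method = "ICA", k = 3, seed = 4)
  expect_equal(unname(colMeans(d$signatures)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(d$signatures, 2, function(v) sqrt(mean(v^2)))),
               rep(1, 3), tolerance = 1e-8)
  for (j in 1:3) {
    expect_gt(d$signatures[which.max(abs(d$signatures[, j])), j], 0)
  }
  cc <- cor(d$signatures)
  expect_true(all(abs(cc[upper.tri(cc)]) <= 0.05))
})

test_that("on pure Gaussian data the unmixing stays orthogonal (decorrelated output)", {
  x <- gaussian_matrix(1000, 40, seed = 6)
  d <- suppressWarnings(decompose_expression(x, method = "ICA", k = 4, seed = 6))
  # symmetric decorrelation enforces orthonormal unmixing, hence
  # uncorrelated unit-variance signatures regardless of convergence
  expect_equal(unname(crossprod(d$signatures)) / nrow(x), diag(4), tolerance = 1e-6)
})

test_that("decompositions are deterministic under a fixed seed", {
  sim <- simulate_expression(n_genes = 400, n_samples = 40, true_k = 2,
                             module_size = 40, seed = 9)
  for (m in c("ICA", "IPCA")) {
    d1 <- decompose_expression(sim$x, method = m, k = 2, seed = 123)
    d2 <- decompose_expression(sim$x, method = m, k = 2, seed = 123)
    expect_equal(d1$signatures, d2$signatures, tolerance = 1e-12)
    expect_equal(d1$patterns, d2$patterns, tolerance = 1e-12)
  }
})

test_that("IPCA recovers a rank-1 factor exactly and planted sparse loadings well", {
  set.seed(5)
  s <- rlaplace(300, 2)
  a <- rnorm(12)
  x <- labeled_matrix(s %*% t(a), 300, 12)
  d1 <- decompose_expression(x, method = "IPCA", k = 1, seed = 5)
  expect_equal(abs(cor(d1$signatures[, 1], s)), 1, tolerance = 1e-8)
  # planted sparse super-Gaussian loadings + dense Gaussian noise
  sim <- simulate_expression(seed = 2)
  d2 <- decompose_expression(sim$x, method = "IPCA", k = 3, seed = 2)
  m <- match_components(d2$signatures, sim$truth$signatures)
  expect_true(all(m$abs_r >= 0.9))
})

test_that("signatures %*% patterns reproduces the rank-k PCA reconstruction", {
  mix <- dense_mixture(500, 30, k = 3, seed = 8)
  xc <- sweep(mix$x, 2, colMeans(mix$x))
  sv <- svd(xc)
  pca_k <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  pca_err <- sqrt(sum((xc - pca_k)^2))
  for (m in c("ICA", "IPCA")) {
    d <- decompose_expression(mix$x, method = m, k = 3, seed = 8)
    rec_err <- sqrt(sum((xc - d$signatures %*% d$patterns)^2))
    expect_lte(rec_err, pca_err + 1e-6)
  }
})

test_that("decomposition validates its configuration", {
  x <- gaussian_matrix(50, 10, seed = 10)
  expect_error(decompose_expression(x, method = "ICA", k = 0, seed = 1), "positive")
  expect_error(decompose_expression(x, method = "ICA", k = 11, seed = 1), "min\\(n_genes")
  expect_error(decompose_expression(x, method = "ICA", k = 2, alpha = 0.5, seed = 1), "alpha")
  expect_error(decompose_expression(x, method = "ICA", k = 2, alpha = 2.5, seed = 1), "alpha")
  expect_error(decompose_expression(x, method = "PCA", k = 2, seed = 1))
  # rank guard: 3 components from a rank-2 matrix
  set.seed(3)
  r2 <- labeled_matrix(matrix(rnorm(40), 20, 2) %*% matrix(rnorm(10), 2, 5), 20, 5)
  expect_error(decompose_expression(r2, method = "ICA", k = 3, seed = 1), "rank")
})

test_that("decomposition writer emits labeled TSVs and a JSON config sidecar", {
  mix <- dense_mixture(60, 12, k = 3, seed = 13)
  d <- decompose_expression(mix$x, method = "ICA", k = 3, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_decomposition(d, dir)
  sig <- read_expression(paths[["signatures"]])
  expect_equal(sig, d$signatures, tolerance = 1e-12)
  pat <- read_expression(paths[["patterns"]])
  expect_equal(pat, d$patterns, tolerance = 1e-12)
  cfg <- jsonlite::read_json(paths[["config"]])
  expect_identical(cfg$method, "ICA")
  expect_identical(cfg$k, 3L)
  expect_true(cfg$converged)
})
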