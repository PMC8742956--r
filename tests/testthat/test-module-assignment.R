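test_that("the tail-FDR fit is calibrated on pure-null signatures", {
  ok <- vapply(1:5, function(s) {
    set.seed(s)
    w <- rnorm(5000)
    fit <- fit_tail_fdr(w)
    fit$eta0 >= 0.95 && min(fit$fdr) > 0.001
  }, logical(1))
  expect_true(all(ok))
})

test_that("a planted spike is isolated exactly by both assigners", {
  set.seed(1)
  w <- c(rnorm(4950), rep(10, 50))
  names(w) <- sprintf("g%04d", seq_along(w))
  spike <- sprintf("g%04d", 4951:5000)
  fit <- fit_tail_fdr(w)
  expect_true(all(fit$fdr[spike] < 0.001))
  expect_gte(fit$eta0, 0.95)
  expect_lte(fit$eta0, 1)
  expect_setequal(names(which(assign_fdr(w, 0.001))), spike)
  expect_setequal(names(which(assign_zscore(w, 3))), spike)
})

test_that("tail-FDR is location-scale invariant and monotone in |z|", {
  set.seed(2)
  w <- c(rnorm(900), rlaplace(100, 4))
  f1 <- fit_tail_fdr(w)
  f2 <- fit_tail_fdr(7 * w + 100)
  expect_equal(f1$fdr, f2$fdr, tolerance = 1e-8)
  o <- order(abs(f1$z))
  expect_true(all(diff(f1$fdr[o]) <= 1e-12))
})

test_that("assignments nest with their thresholds", {
  set.seed(3)
  w <- c(rnorm(2000), rlaplace(100, 5))
  names(w) <- sprintf("g%04d", seq_along(w))
  a1 <- assign_fdr(w, 0.0005)
  a2 <- assign_fdr(w, 0.01)
  expect_true(all(!a1 | a2)) # q1 <= q2 => membership subset
  z1 <- assign_zscore(w, 2)
  z2 <- assign_zscore(w, 3.5)
  expect_true(all(!z2 | z1)) # larger sigma cut => subset
})

test_that("the z-score assigner matches its analytic tail mass and hand example", {
  set.seed(4)
  frac <- mean(assign_zscore(rnorm(1e5), 3))
  expect_equal(frac, 2 * pnorm(-3), tolerance = 0.0010 / 0.0027)
  # 99 zeros and a single 1: the outlier's z is (1 - .01)/.0995 ~ 9.95
  w <- c(rep(0, 99), 1)
  names(w) <- sprintf("g%03d", 1:100)
  hit <- assign_zscore(w, 3)
  expect_identical(names(which(hit)), "g100")
  expect_error(assign_zscore(w, 0), "positive")
  expect_error(assign_zscore(rep(1, 100), 3), "zero variance")
})

test_that("degenerate or tiny signatures are rejected by the FDR fit", {
  expect_error(fit_tail_fdr(rnorm(20)), "at least 50")
  expect_error(fit_tail_fdr(rep(1, 100)), "median absolute deviation")
  expect_error(assign_fdr(rnorm(100), q = 0), "between 0 and 1")
  expect_error(assign_fdr(rnorm(100), q = 1), "between 0 and 1")
})

test_that("module detection enforces the assigner/backend pairing", {
  sim <- simulate_expression(n_genes = 400, n_samples = 40, true_k = 2,
                             module_size = 40, seed = 5)
  d_ipca <- decompose_expression(normalize_expression(sim$x), "IPCA", k = 2, seed = 5)
  expect_error(detect_modules(d_ipca, method = "ICA-FDR"), "pairs with")
  expect_error(detect_modules(d_ipca, method = "ICA-Zscore"), "pairs with")
  d_ica <- decompose_expression(normalize_expression(sim$x), "ICA", k = 2, seed = 5)
  expect_error(detect_modules(d_ica, method = "IPCA-FDR"), "pairs with")
})

test_that("detected modules overlap and recover the planted memberships", {
  sim <- simulate_expression(seed = 6)
  xn <- normalize_expression(sim$x)
  d <- decompose_expression(xn, "ICA", k = 3, seed = 6)
  m <- detect_modules(d, method = "ICA-FDR")
  expect_identical(m$module_ids, paste0("oM", 1:3))
  mm <- match_modules(m$membership, sim$truth$membership)
  expect_true(all(mm$jaccard >= 0.75))
  # overlap contract: planted shared genes surface in >= 2 detected modules
  expect_gte(sum(rowSums(m$membership) >= 2), 1L)
  # membership rows can sum above 1: overlap is realizable by construction
  expect_gt(max(rowSums(m$membership)), 1)
})

test_that("signatures that assign nothing are dropped with renumbering", {
  set.seed(7)
  sigs <- cbind(
    c(rnorm(200), rep(12, 10)),      # clear spike module
    rep(c(1, -1), 105)               # bounded |z| <= 1: empty at 3 sigma
  )
  rownames(sigs) <- sprintf("g%03d", 1:210)
  colnames(sigs) <- c("C1", "C2")
  d <- fake_decomposition(sigs, method = "ICA")
  expect_warning(
    m <- detect_modules(d, fake_filter(1:2), method = "ICA-Zscore", threshold = 3),
    "dropped"
  )
  expect_identical(m$module_ids, "oM1")
  expect_identical(m$component_index, 1L)
  expect_true(all(m$membership[, 1] == (sigs[, 1] > 10)))
})

test_that("module writers emit consistent wide and long views", {
  sim <- simulate_expression(n_genes = 500, n_samples = 50, true_k = 3,
                             module_size = 50, seed = 8)
  d <- decompose_expression(normalize_expression(sim$x), "ICA", k = 3, seed = 8)
  m <- detect_modules(d, method = "ICA-FDR")
  dir <- withr::local_tempdir()
  paths <- write_modules(m, dir)
  wide <- read_expression(paths[["wide"]])
  expect_equal(wide, m$membership * 1)
  long <- utils::read.table(paths[["long"]], header = TRUE, sep = "\t")
  expect_identical(nrow(long), sum(m$membership))
})
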