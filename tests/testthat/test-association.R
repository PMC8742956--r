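module_set_from_patterns <- function(patterns) {
  k <- nrow(patterns)
  genes <- sprintf("g%03d", 1:20)
  structure(
    list(
      membership = matrix(TRUE, 20, k, dimnames = list(genes, rownames(patterns))),
      weights = matrix(rnorm(20 * k), 20, k, dimnames = list(genes, rownames(patterns))),
      patterns = patterns,
      module_ids = rownames(patterns),
      component_index = seq_len(k),
      method = "ICA-FDR", threshold = 0.001
    ),
    class = "module_set"
  )
}

test_that("a feature equal to a pattern correlates perfectly; orthogonal ones do not", {
  set.seed(1)
  pat <- matrix(rnorm(2 * 200), 2, 200,
                dimnames = list(c("oM1", "oM2"), sprintf("s%03d", 1:200)))
  m <- module_set_from_patterns(pat)
  raw <- rnorm(200)
  ortho <- residuals(lm(raw ~ pat[1, ]))
  cli <- data.frame(self = pat[1, ], ortho = ortho,
                    row.names = colnames(pat))
  at <- module_trait_correlation(m, cli)
  expect_equal(unname(at$r["oM1", "self"]), 1, tolerance = 1e-12)
  expect_lt(at$p["oM1", "self"], 1e-100)
  expect_lt(abs(at$r["oM1", "ortho"]), 0.15)
  expect_gt(at$p["oM1", "ortho"], 0.01)
  expect_true(all(at$n_used == 200))
  expect_true(all(at$p_adj >= at$p - 1e-15))
})

test_that("starved module-feature cells go missing with a warning, not an error", {
  set.seed(2)
  pat <- matrix(rnorm(100), 1, 100,
                dimnames = list("oM1", sprintf("s%03d", 1:100)))
  m <- module_set_from_patterns(pat)
  sparse <- c(1.2, -0.5, rep(NA_real_, 98))
  cli <- data.frame(sparse = sparse, fine = rnorm(100), row.names = colnames(pat))
  expect_warning(at <- module_trait_correlation(m, cli), "fewer than 3 complete")
  expect_true(is.na(at$r["oM1", "sparse"]))
  expect_identical(at$n_used["oM1", "sparse"], 2L)
  expect_false(is.na(at$r["oM1", "fine"]))
})

test_that("categorical features are refused rather than silently coerced", {
  pat <- matrix(rnorm(30), 1, 30, dimnames = list("oM1", sprintf("s%03d", 1:30)))
  m <- module_set_from_patterns(pat)
  cli <- data.frame(stage = factor(sample(c("I", "II"), 30, TRUE)),
                    row.names = colnames(pat))
  expect_error(module_trait_correlation(m, cli), "non-numeric")
})

test_that("association aligns samples by id, not position", {
  set.seed(3)
  pat <- matrix(rnorm(50), 1, 50, dimnames = list("oM1", sprintf("s%03d", 1:50)))
  m <- module_set_from_patterns(pat)
  cli <- data.frame(self = pat[1, ], row.names = colnames(pat))
  shuffled <- cli[sample(1:50), , drop = FALSE]
  at <- module_trait_correlation(m, shuffled)
  expect_equal(unname(at$r["oM1", "self"]), 1, tolerance = 1e-12)
})

test_that("association p-values are uniform under a permuted-feature null", {
  set.seed(4)
  n <- 200
  pat <- matrix(rnorm(n), 1, n, dimnames = list("oM1", sprintf("s%03d", 1:n)))
  m <- module_set_from_patterns(pat)
  base <- rnorm(n)
  perms <- replicate(500, sample(base))
  cli <- as.data.frame(perms)
  names(cli) <- sprintf("p%03d", 1:500)
  rownames(cli) <- colnames(pat)
  at <- module_trait_correlation(m, cli)
  ks <- suppressWarnings(ks.test(as.vector(at$p), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("eigengenes reduce to the standardized profile on rank-1 gene sets", {
  set.seed(5)
  prof <- rnorm(30)
  x <- rbind(
    g1 = 2 * prof + 1,
    g2 = -3 * prof + 5,
    g3 = prof,
    g4 = rnorm(30)
  )
  colnames(x) <- sprintf("s%03d", 1:30)
  # identical (up to affine) rows: eigengene is that profile
  e <- compute_eigengene(x, c("g1", "g3"))
  expect_equal(abs(cor(e, prof)), 1, tolerance = 1e-10)
  # two anti-correlated genes still give |r| = 1 with each
  e2 <- compute_eigengene(x, c("g1", "g2"))
  expect_equal(abs(cor(e2, x["g1", ])), 1, tolerance = 1e-10)
  expect_equal(abs(cor(e2, x["g2", ])), 1, tolerance = 1e-10)
  # singleton set: the gene's standardized profile
  e3 <- compute_eigengene(x, "g4")
  expect_equal(unname(e3), unname((x["g4", ] - mean(x["g4", ])) /
                                    sqrt(mean((x["g4", ] - mean(x["g4", ]))^2))),
               tolerance = 1e-12)
  expect_error(compute_eigengene(x, "missing_gene"), "absent")
})

test_that("eigengene sign follows the mean standardized profile of the set", {
  sim <- simulate_expression(n_genes = 300, n_samples = 40, true_k = 1,
                             module_size = 50, seed = 6)
  members <- names(which(sim$truth$membership[, 1]))
  e <- compute_eigengene(sim$x, members)
  subn <- normalize_expression(sim$x[members, ])
  expect_gt(cor(e, colMeans(subn)), 0)
  expect_equal(mean((e - mean(e))^2), 1, tolerance = 1e-10)
})

test_that("pattern-eigengene comparison flags captured and missed structure", {
  set.seed(7)
  pat <- matrix(rnorm(3 * 60), 3, 60,
                dimnames = list(paste0("oM", 1:3), sprintf("s%03d", 1:60)))
  eg <- t(pat)
  colnames(eg) <- paste0("ME", 1:3)
  cmp <- compare_patterns_to_eigengenes(pat, eg, r_cut = 0.8)
  expect_equal(unname(diag(cmp$abs_r)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(cmp$eigengene_captured))
  expect_false(any(cmp$pattern_missed))
  expect_equal(cmp$pct_patterns_captured, 100)
  # an extra pure-noise eigengene is missed
  eg2 <- cbind(eg, noise = rnorm(60))
  cmp2 <- compare_patterns_to_eigengenes(pat, eg2, r_cut = 0.8)
  expect_false(cmp2$eigengene_captured[["noise"]])
  expect_equal(cmp2$pct_eigengenes_captured, 75)
  expect_error(compare_patterns_to_eigengenes(pat, eg, r_cut = 1.2), "r_cut")
})

test_that("correlations are invariant to affine transforms of either side", {
  set.seed(8)
  pat <- matrix(rnorm(2 * 40), 2, 40,
                dimnames = list(paste0("oM", 1:2), sprintf("s%03d", 1:40)))
  eg <- matrix(rnorm(40 * 2), 40, 2,
               dimnames = list(colnames(pat), paste0("ME", 1:2)))
  c1 <- compare_patterns_to_eigengenes(pat, eg, r_cut = 0.5)
  c2 <- compare_patterns_to_eigengenes(-3 * pat + 2, eg * 10 - 4, r_cut = 0.5)
  expect_equal(c1$abs_r, c2$abs_r, tolerance = 1e-10)
})
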