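# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read.

# small labeled matrix with given entries (genes x samples)
labeled_matrix <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# i.i.d. Gaussian expression-like matrix
gaussian_matrix <- function(n_genes, n_samples, seed, sd = 1) {
  set.seed(seed)
  labeled_matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples)
}

# Laplace(0, scale) draws
rlaplace <- function(n, scale = 1) {
  scale * rexp(n) * sample(c(-1, 1), n, replace = TRUE)
}

# noise-free mixture X = S %*% A with Laplace signature columns and
# Gaussian patterns; returns the matrix plus the planted parts
dense_mixture <- function(n_genes, n_samples, k, seed, scale = 1) {
  set.seed(seed)
  s <- matrix(rlaplace(n_genes * k, scale), n_genes, k)
  a <- matrix(rnorm(k * n_samples), k, n_samples)
  x <- s %*% a
  dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  list(x = x, s = s, a = a)
}

# hand-built decomposition object for tests that bypass the ICA path
fake_decomposition <- function(signatures, method = "ICA") {
  k <- ncol(signatures)
  patterns <- matrix(rnorm(k * 10), k, 10,
                     dimnames = list(paste0("C", seq_len(k)), sprintf("s%03d", 1:10)))
  structure(
    list(
      signatures = signatures, patterns = patterns,
      method = method, k = k, alpha = 1, max_iter = 200L, tol = 1e-4,
      seed = 1L, converged = TRUE, n_iter = 1L,
      col_center = rep(0, 10)
    ),
    class = "decomposition"
  )
}

fake_filter <- function(kept, kurt = NULL, threshold = 3) {
  if (is.null(kurt)) kurt <- rep(10, max(kept))
  structure(
    list(kurtosis_values = kurt, kept = kept, threshold = threshold),
    class = "signature_filter"
  )
}
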