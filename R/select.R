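# Permutation-based choice of the number of components (parallel analysis)
# and the decomposition-method recommendation.

#' Choose the number of components by permutation parallel analysis
#'
#' The observed statistic for candidate j is the fraction of total variance
#' carried by the j-th singular value of the normalized matrix. For each of
#' B permutations the entries of every gene row are independently shuffled
#' across samples — destroying gene-gene correlation while preserving each
#' gene's marginal distribution (and, for standardized rows, the total
#' variance) — and the statistic is recomputed. The empirical p-value per
#' candidate uses the +1 correction, so it is never exactly zero:
#' `p_j = (1 + #permutations with stat_j >= observed_j) / (B + 1)`.
#' The chosen k is the length of the initial run of candidates significant
#' at `alpha` (0 when the first candidate already fails).
#'
#' @param x numeric matrix, genes x samples, gene-standardized.
#' @param k_max largest candidate count; default `min(dim(x))`, capped there.
#' @param B number of permutations, at least 19 (p-value resolution);
#'   default 50.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param seed integer seed driving the permutations (and, when
#'   `recommend = TRUE`, the decompositions).
#' @param recommend logical; also run [recommend_method()] at the chosen k
#'   (skipped when the chosen k is 0).
#' @return object of class `"component_selection"`: `candidate_counts`,
#'   `observed_stat`, `perm_pvalues`, `chosen_k`, `recommended_method`
#'   (`NA` when not computed), `B`, `alpha`, `seed`.
#' @export
select_components <- function(x, k_max = NULL, B = 50L, alpha = 0.05,
                              seed = 1L, recommend = TRUE) {
  validate_expression(x)
  if (is.null(k_max)) k_max <- min(dim(x))
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("k_max must be at least 1")
  if (k_max > min(dim(x))) stop("k_max must not exceed min(dim(x)) = ", min(dim(x)))
  B <- as.integer(B)
  if (B < 19L) stop("B must be at least 19: fewer permutations make the p-value resolution too coarse")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")

  obs <- variance_fractions(x, k_max)
  exceed <- integer(k_max)
  with_seed(seed, {
    n <- ncol(x)
    for (b in seq_len(B)) {
      xp <- x
      for (i in seq_len(nrow(x))) xp[i, ] <- x[i, sample.int(n)]
      stat <- variance_fractions(xp, k_max)
      exceed <- exceed + (stat >= obs)
    }
  })
  pval <- (1 + exceed) / (B + 1)
  sig <- pval < alpha
  chosen_k <- if (!sig[1L]) 0L else {
    runs <- which(!sig)
    if (length(runs) == 0L) k_max else runs[1L] - 1L
  }

  rec <- NA_character_
  if (recommend && chosen_k >= 1L) {
    rec <- recommend_method(x, chosen_k, seed = seed)
  }

  structure(
    list(
      candidate_counts = seq_len(k_max),
      observed_stat = obs,
      perm_pvalues = pval,
      chosen_k = chosen_k,
      recommended_method = rec,
      B = B, alpha = alpha, seed = as.integer(seed)
    ),
    class = "component_selection"
  )
}

# fraction of total variance per singular value, via the small-side Gram
# matrix (total sum of squares is the sum of all eigenvalues)
variance_fractions <- function(x, k_max) {
  g <- if (ncol(x) <= nrow(x)) crossprod(x) else tcrossprod(x)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  (ev / sum(ev))[seq_len(k_max)]
}

#' Recommend a decomposition method at a given component count
#'
#' Runs both backends at `k` and counts how many of each one's signatures
#' pass the kurtosis cut (Pearson kurtosis >= `kurtosis_threshold`). The
#' method retaining more non-Gaussian signatures is recommended; ties go to
#' IPCA, the backend more robust to dense noise.
#'
#' @param x numeric matrix, genes x samples, gene-standardized.
#' @param k number of components, at least 1. A k of 0 (no non-random
#'   structure found) is an error: there is nothing to decompose.
#' @param seed integer seed passed to both decompositions.
#' @param kurtosis_threshold retention cut on the Pearson-kurtosis scale;
#'   default 3 (the Gaussian reference value).
#' @return `"ICA"` or `"IPCA"`.
#' @export
recommend_method <- function(x, k, seed = 1L, kurtosis_threshold = 3) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) {
    stop("k must be at least 1: no non-random structure was found ",
         "(chosen k = 0), so there is nothing to decompose")
  }
  n_pass <- vapply(c("ICA", "IPCA"), function(m) {
    d <- suppressWarnings(decompose_expression(x, method = m, k = k, seed = seed))
    sum(apply(d$signatures, 2L, kurtosis) >= kurtosis_threshold)
  }, numeric(1L))
  if (n_pass[["ICA"]] > n_pass[["IPCA"]]) "ICA" else "IPCA"
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf(
    "Component selection: B = %d permutations, alpha = %g, seed = %d\n",
    x$B, x$alpha, x$seed
  ))
  cat(sprintf("  chosen k = %d; recommended method = %s\n",
              x$chosen_k, x$recommended_method))
  df <- as.data.frame(x)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat("  ... (", nrow(df) - 10L, " more candidates)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.component_selection <- function(x, ...) {
  data.frame(
    candidate = x$candidate_counts,
    variance_fraction = x$observed_stat,
    perm_pvalue = x$perm_pvalues
  )
}
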