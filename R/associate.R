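# Module-trait association and eigengene comparison.
#
# A module is summarized for sample-level analysis by its pattern (the
# sample-space component paired with its signature), and each pattern is
# correlated against each clinical feature with Pearson's r over
# pairwise-complete samples. For benchmarking against hard clusterings
# (WGCNA-style), module eigengenes — first principal components of a gene
# set's standardized submatrix — can be computed and cross-correlated with
# the patterns to see which side misses which structure.

#' Correlate module patterns with clinical features
#'
#' Clinical features must already be numeric (ordinal encodings are fine);
#' factors and character columns are refused rather than silently coerced.
#' Samples are aligned by id, never by position. Each module-feature cell
#' reports Pearson's r over the pairwise-complete samples, a two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom, a Benjamini-Hochberg adjusted p (computed across all cells),
#' and the sample count used. Cells with fewer than 3 complete pairs are
#' set to `NA` with a warning.
#'
#' @param m `"module_set"` object (its patterns carry the sample ids).
#' @param clinical data.frame of numeric features with sample ids as row
#'   names; may contain missing values.
#' @return object of class `"association_table"`: matrices `r`, `p`,
#'   `p_adj`, `n_used` (modules x features).
#' @export
module_trait_correlation <- function(m, clinical) {
  stopifnot(inherits(m, "module_set"))
  if (!is.data.frame(clinical)) stop("clinical must be a data.frame with sample ids as rownames")
  if (is.null(rownames(clinical))) stop("clinical table must carry sample ids as rownames")
  not_num <- !vapply(clinical, is.numeric, logical(1L))
  if (any(not_num)) {
    stop("non-numeric clinical feature(s): ",
         paste(names(clinical)[not_num], collapse = ", "),
         ". Encode categorical features numerically before association.")
  }
  shared <- intersect(colnames(m$patterns), rownames(clinical))
  if (length(shared) < 3L) stop("fewer than 3 samples shared between patterns and clinical table")
  pat <- m$patterns[, shared, drop = FALSE]
  cli <- clinical[shared, , drop = FALSE]

  mods <- rownames(pat)
  feats <- names(cli)
  r <- p <- matrix(NA_real_, length(mods), length(feats), dimnames = list(mods, feats))
  n_used <- matrix(NA_integer_, length(mods), length(feats), dimnames = list(mods, feats))
  starved <- character(0)
  for (i in seq_along(mods)) {
    for (j in seq_along(feats)) {
      y <- cli[[j]]
      ok <- !is.na(y)
      n <- sum(ok)
      n_used[i, j] <- n
      if (n < 3L) {
        starved <- c(starved, paste0(mods[i], "~", feats[j]))
        next
      }
      rij <- stats::cor(pat[i, ok], y[ok])
      r[i, j] <- rij
      tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      p[i, j] <- max(2 * stats::pt(-abs(tt), df = n - 2), .Machine$double.xmin)
    }
  }
  if (length(starved) > 0L) {
    warning("fewer than 3 complete pairs for: ",
            paste(unique(starved), collapse = ", "), "; cells set to NA")
  }
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p), dimnames = dimnames(p))
  structure(
    list(r = r, p = p, p_adj = p_adj, n_used = n_used),
    class = "association_table"
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat("Module-trait association (Pearson r; two-sided p, BH-adjusted in parentheses):\n")
  txt <- matrix(sprintf("%.3f [p=%.2g (%.2g)]", x$r, x$p, x$p_adj),
                nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  print(txt, quote = FALSE)
  invisible(x)
}

#' Module eigengene: first principal component of a gene set
#'
#' Standardizes the submatrix over the gene set gene-wise and returns its
#' first right singular vector across samples, scaled to unit (population)
#' variance and sign-oriented to correlate positively with the set's mean
#' standardized profile. A singleton gene set returns that gene's
#' standardized profile; constant genes inside larger sets are dropped
#' with a warning.
#'
#' @param x numeric matrix, genes x samples (raw or normalized scale).
#' @param genes character vector of gene ids present in `x`.
#' @return named numeric vector over samples.
#' @export
compute_eigengene <- function(x, genes) {
  if (length(genes) == 0L) stop("gene set is empty")
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes) > 0L) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  sub <- x[genes, , drop = FALSE]
  if (length(genes) == 1L) {
    v <- drop(sub)
    s <- pop_sd(v)
    if (s == 0) stop("singleton gene set with zero variance")
    return(stats::setNames((v - mean(v)) / s, colnames(x)))
  }
  s <- row_pop_sd(sub)
  if (any(s == 0)) {
    warning("dropping ", sum(s == 0), " constant gene(s) from eigengene computation")
    sub <- sub[s > 0, , drop = FALSE]
    if (nrow(sub) == 0L) stop("all genes in the set are constant")
    if (nrow(sub) == 1L) return(compute_eigengene(x, rownames(sub)))
    s <- s[s > 0]
  }
  subn <- (sub - rowMeans(sub)) / s
  sv <- svd(subn, nu = 0L, nv = 1L)
  e <- drop(sv$v[, 1L])
  e <- e / pop_sd(e)
  if (stats::cor(e, colMeans(subn)) < 0) e <- -e
  stats::setNames(e, colnames(x))
}

#' Cross-correlate decomposition patterns with external module eigengenes
#'
#' Computes the full |Pearson r| matrix between the patterns of a
#' decomposition (or module set) and a set of eigengenes from an external
#' clustering, aligned by sample id. A pattern is flagged `missed` when no
#' eigengene reaches `r_cut` against it (structure the external clustering
#' did not represent); an eigengene is flagged `captured` when some pattern
#' reaches `r_cut`. Summary percentages are reported on both sides.
#'
#' @param patterns a `"decomposition"`, a `"module_set"`, or a plain
#'   numeric matrix (components x samples with sample ids as colnames).
#' @param eigengenes numeric matrix samples x eigengenes (sample ids as
#'   rownames), or a named list/data.frame of sample-named vectors.
#' @param r_cut correlation cut in (0, 1); conventional choices are 0.4
#'   for small gene panels and 0.8 for genome-scale runs.
#' @return object of class `"pattern_comparison"`: `abs_r` (patterns x
#'   eigengenes), `pattern_missed`, `eigengene_captured`,
#'   `pct_patterns_captured`, `pct_eigengenes_captured`, `r_cut`.
#' @export
compare_patterns_to_eigengenes <- function(patterns, eigengenes, r_cut = 0.8) {
  if (inherits(patterns, "decomposition") || inherits(patterns, "module_set")) {
    patterns <- patterns$patterns
  }
  patterns <- as.matrix(patterns)
  if (is.data.frame(eigengenes)) eigengenes <- as.matrix(eigengenes)
  if (is.list(eigengenes)) {
    eigengenes <- do.call(cbind, eigengenes)
  }
  eigengenes <- as.matrix(eigengenes)
  if (!is.numeric(r_cut) || length(r_cut) != 1L || r_cut <= 0 || r_cut >= 1) {
    stop("r_cut must lie strictly between 0 and 1")
  }
  shared <- intersect(colnames(patterns), rownames(eigengenes))
  if (length(shared) < 3L) stop("fewer than 3 samples shared between patterns and eigengenes")
  a <- abs(stats::cor(t(patterns[, shared, drop = FALSE]),
                      eigengenes[shared, , drop = FALSE]))
  missed <- apply(a, 1L, max) < r_cut
  captured <- apply(a, 2L, max) >= r_cut
  structure(
    list(
      abs_r = a,
      pattern_missed = missed,
      eigengene_captured = captured,
      pct_patterns_captured = 100 * mean(!missed),
      pct_eigengenes_captured = 100 * mean(captured),
      r_cut = r_cut
    ),
    class = "pattern_comparison"
  )
}

#' @export
print.pattern_comparison <- function(x, ...) {
  cat(sprintf("Pattern vs eigengene comparison at |r| >= %g:\n", x$r_cut))
  cat(sprintf("  %.1f%% of patterns captured by some eigengene; %.1f%% of eigengenes captured by some pattern\n",
              x$pct_patterns_captured, x$pct_eigengenes_captured))
  if (any(x$pattern_missed)) {
    cat("  missed patterns: ", paste(names(which(x$pattern_missed)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
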