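# Gene-to-module assignment: convert each retained signature into an
# overlapping gene module.
#
# Two assigners are provided. The tail-area FDR route models a signature's
# gene weights as a two-component mixture (a Gaussian null fitted around
# the median plus an alternative in the tails) and assigns genes whose
# tail-area FDR falls below a stringent threshold (default 0.001). The
# z-score route standardizes the weights and assigns genes beyond a
# k-sigma cut (default 3 sigma). Because every signature is assigned
# independently, a gene may land in zero, one, or several modules —
# overlap is permitted by construction.

#' Fit a tail-area FDR mixture to a signature
#'
#' The null (Gaussian) component is fitted around the median of the weight
#' distribution: its centre is the median and its scale the normal-consistent
#' MAD (median absolute deviation times 1.4826), both robust to the
#' heavy-tail alternative. The null proportion `eta0` is estimated by
#' comparing the empirical mass of the central 75% window of |z| with the
#' mass a standard Gaussian would put there, capped at 1. The tail-area FDR
#' of gene g with robust score `z_g` is
#' `min(1, eta0 * 2 * (1 - Phi(|z_g|)) / ecdf(|z| >= |z_g|))`,
#' then smoothed to be monotone non-increasing in |z| by a cumulative
#' maximum running from the tails inward. Median/MAD standardization makes
#' the whole fit invariant to location-scale transforms of the signature.
#'
#' @param w numeric vector of gene weights, length >= 50, non-constant.
#' @return object of class `"tail_fdr"`: `eta0`, `null_center`,
#'   `null_scale`, `z` (robust scores), `fdr` (per-gene tail-area FDR,
#'   named like `w`).
#' @export
fit_tail_fdr <- function(w) {
  if (!is.numeric(w)) stop("signature weights must be numeric")
  if (length(w) < 50L) stop("tail-FDR fitting needs at least 50 genes")
  if (anyNA(w) || any(!is.finite(w))) stop("signature weights must be finite")
  med <- stats::median(w)
  scl <- stats::mad(w, center = med)
  if (scl == 0) stop("degenerate signature: median absolute deviation is zero")
  z <- (w - med) / scl
  az <- abs(z)
  n <- length(w)
  h <- stats::quantile(az, 0.75, names = FALSE)
  expected_mass <- 2 * stats::pnorm(h) - 1
  eta0 <- if (expected_mass <= 0) 1 else min(1, 0.75 / expected_mass)
  # empirical two-sided tail fraction: share of genes at least as extreme
  frac_ge <- (n - rank(az, ties.method = "min") + 1) / n
  fdr <- pmin(1, eta0 * 2 * stats::pnorm(-az) / frac_ge)
  # monotone non-increasing in |z|: sweep from the extremes inward
  o <- order(az, decreasing = TRUE)
  fdr[o] <- cummax(fdr[o])
  names(fdr) <- names(w)
  structure(
    list(eta0 = eta0, null_center = med, null_scale = scl, z = z, fdr = fdr),
    class = "tail_fdr"
  )
}

#' Assign genes to a module by tail-area FDR
#'
#' @param w numeric vector of gene weights (one signature).
#' @param q FDR threshold in (0, 1); default 0.001, a deliberately stringent
#'   cut that picks only clear tail genes. Assignment is strict
#'   (`fdr < q`).
#' @return named logical vector: module membership per gene.
#' @export
assign_fdr <- function(w, q = 0.001) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must lie strictly between 0 and 1")
  }
  fit <- fit_tail_fdr(w)
  fit$fdr < q
}

#' Assign genes to a module by z-score
#'
#' Weights are standardized with the mean and population standard deviation
#' of the signature; genes with `|z| > k_sigma` (strict) are assigned.
#'
#' @param w numeric vector of gene weights (one signature).
#' @param k_sigma positive cut in standard deviations; default 3, which
#'   admits only the few genes far out in either tail.
#' @return named logical vector: module membership per gene.
#' @export
assign_zscore <- function(w, k_sigma = 3) {
  if (!is.numeric(w)) stop("signature weights must be numeric")
  if (!is.numeric(k_sigma) || length(k_sigma) != 1L || k_sigma <= 0) {
    stop("k_sigma must be a single positive number")
  }
  s <- pop_sd(w)
  if (s == 0) stop("degenerate signature: zero variance")
  z <- (w - mean(w)) / s
  out <- abs(z) > k_sigma
  names(out) <- names(w)
  out
}

#' Detect overlapping co-expressed gene modules
#'
#' Applies the per-signature assigner over the retained (kurtosis-passing)
#' signatures of a decomposition and collects the results into a module
#' set. The assigner must match the backend: `"ICA-FDR"` and `"ICA-Zscore"`
#' post-process an ICA decomposition, `"IPCA-FDR"` an IPCA one. Signatures
#' that assign no gene are dropped with a warning and the surviving modules
#' renumbered `oM1, oM2, ...` in retained-signature order.
#'
#' @param d `"decomposition"` object.
#' @param filter `"signature_filter"` from [filter_signatures()]; computed
#'   at the default threshold of 3 when omitted.
#' @param method one of `"ICA-FDR"`, `"ICA-Zscore"`, `"IPCA-FDR"`.
#' @param threshold assigner threshold: FDR cut for the FDR routes (default
#'   0.001), sigma cut for the z-score route (default 3).
#' @return object of class `"module_set"`: `membership` (logical genes x
#'   modules), `weights` (signature loadings, genes x modules), `patterns`
#'   (modules x samples), `module_ids`, `component_index` (which signature
#'   each module came from), `method`, `threshold`.
#' @export
detect_modules <- function(d, filter = NULL,
                           method = c("ICA-FDR", "ICA-Zscore", "IPCA-FDR"),
                           threshold = NULL) {
  stopifnot(inherits(d, "decomposition"))
  method <- match.arg(method)
  backend <- if (method == "IPCA-FDR") "IPCA" else "ICA"
  if (d$method != backend) {
    stop("post-processing method '", method, "' pairs with a ", backend,
         " decomposition, but this decomposition used ", d$method,
         " (ICA takes ICA-FDR or ICA-Zscore; IPCA takes IPCA-FDR)")
  }
  if (is.null(filter)) filter <- filter_signatures(d)
  stopifnot(inherits(filter, "signature_filter"))
  if (is.null(threshold)) threshold <- if (method == "ICA-Zscore") 3 else 0.001

  kept <- filter$kept
  memb <- vapply(kept, function(j) {
    w <- d$signatures[, j]
    if (method == "ICA-Zscore") assign_zscore(w, threshold) else assign_fdr(w, threshold)
  }, logical(nrow(d$signatures)))
  memb <- matrix(memb, nrow = nrow(d$signatures),
                 dimnames = list(rownames(d$signatures), NULL))

  nonempty <- colSums(memb) > 0L
  if (!all(nonempty)) {
    warning(sum(!nonempty), " signature(s) assigned no gene at threshold ",
            threshold, " and were dropped; modules renumbered")
  }
  if (!any(nonempty)) stop("every retained signature produced an empty module; relax the threshold")
  kept <- kept[nonempty]
  memb <- memb[, nonempty, drop = FALSE]
  ids <- paste0("oM", seq_along(kept))
  colnames(memb) <- ids
  weights <- d$signatures[, kept, drop = FALSE]
  colnames(weights) <- ids
  patterns <- d$patterns[kept, , drop = FALSE]
  rownames(patterns) <- ids

  structure(
    list(
      membership = memb, weights = weights, patterns = patterns,
      module_ids = ids, component_index = kept,
      method = method, threshold = threshold
    ),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- colSums(x$membership)
  overlap <- sum(rowSums(x$membership) >= 2L)
  cat(sprintf("Module set (%s, threshold %g): %d modules over %d genes\n",
              x$method, x$threshold, length(x$module_ids), nrow(x$membership)))
  cat("  sizes: ", paste(sprintf("%s=%d", x$module_ids, sizes), collapse = ", "), "\n", sep = "")
  cat("  genes in >= 2 modules: ", overlap, "\n", sep = "")
  invisible(x)
}

#' Write a module set to disk
#'
#' Two views are emitted: a wide boolean TSV (genes x modules) and a long
#' TSV (one row per gene-module membership with the signature weight).
#'
#' @param m `"module_set"` object.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_modules <- function(m, dir) {
  stopifnot(inherits(m, "module_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- file.path(dir, "membership.tsv")
  long <- file.path(dir, "modules_long.tsv")
  write_tsv_matrix(m$membership * 1L, wide)
  idx <- which(m$membership, arr.ind = TRUE)
  df <- data.frame(
    gene = rownames(m$membership)[idx[, 1L]],
    module = colnames(m$membership)[idx[, 2L]],
    weight = m$weights[idx]
  )
  df <- df[order(df$module, -abs(df$weight), df$gene), ]
  utils::write.table(df, long, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(wide = wide, long = long))
}
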