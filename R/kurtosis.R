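# Non-Gaussianity screening of signatures.

#' Pearson (non-excess) sample kurtosis
#'
#' `m4 / m2^2` with central moments about the sample mean and no bias
#' correction. On this scale a Gaussian scores 3, so the conventional
#' heavy-tail retention rule "kurtosis >= 3" reads directly. Pearson's
#' inequality guarantees a value >= 1 for any non-degenerate vector, and
#' the statistic is invariant to affine rescaling.
#'
#' @param x numeric vector, length >= 4, non-constant.
#' @return single numeric kurtosis value.
#' @export
kurtosis <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (length(x) < 4L) stop("kurtosis needs at least 4 observations")
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("kurtosis undefined for a zero-variance vector")
  mean((x - m)^4) / m2^2
}

#' Retain heavy-tailed (non-Gaussian) signatures
#'
#' Decomposition components are only meaningful module generators when
#' their gene-weight distribution is heavy-tailed — a few genes in the
#' tails drive the component while the bulk sits near the centre. Kurtosis
#' is computed per signature and only signatures at or above `threshold`
#' (Pearson scale, Gaussian = 3) are retained; their paired patterns follow.
#'
#' @param x a `"decomposition"` object, or a plain numeric matrix whose
#'   columns are signatures.
#' @param threshold positive retention cut; default 3.
#' @return object of class `"signature_filter"`: `kurtosis_values` (one per
#'   signature), `kept` (indices with kurtosis >= threshold, original order),
#'   `threshold`.
#' @export
filter_signatures <- function(x, threshold = 3) {
  s <- if (inherits(x, "decomposition")) x$signatures else as.matrix(x)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  kv <- apply(s, 2L, kurtosis)
  kept <- which(unname(kv) >= threshold)
  if (length(kept) == 0L) {
    stop("no signature passed the kurtosis threshold of ", threshold,
         "; try a different number of components or the other decomposition method")
  }
  structure(
    list(kurtosis_values = kv, kept = kept, threshold = threshold),
    class = "signature_filter"
  )
}

#' @export
print.signature_filter <- function(x, ...) {
  cat(sprintf("Signature filter: %d of %d signatures kept (kurtosis >= %g)\n",
              length(x$kept), length(x$kurtosis_values), x$threshold))
  print(data.frame(
    signature = seq_along(x$kurtosis_values),
    kurtosis = x$kurtosis_values,
    kept = seq_along(x$kurtosis_values) %in% x$kept
  ), row.names = FALSE)
  invisible(x)
}
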