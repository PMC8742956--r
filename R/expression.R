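# Expression-matrix ingestion, validation and pre-processing.
#
# The canonical container is a plain numeric matrix with genes as rows and
# samples as columns, carrying unique dimnames. Pre-processing mirrors the
# usual expression-QC workflow: drop outlier samples by standardized
# sample-network connectivity, then centre and standardize every gene across
# samples so downstream decompositions see scale-free rows.

#' Validate a gene-expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with at least 2 genes (rows) and 3 samples (columns), unique row
#' and column names, and finite entries (unless missing values are
#' explicitly permitted by the caller).
#'
#' @param x numeric matrix, genes x samples.
#' @param allow_missing logical; permit `NA` entries (non-finite values other
#'   than `NA` are always rejected).
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x, allow_missing = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  if (nrow(x) < 2L) stop("need at least 2 genes (rows)")
  if (ncol(x) < 3L) stop("need at least 3 samples (columns)")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids in rownames")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in colnames")
  if (!allow_missing && anyNA(x)) {
    stop("missing values present in expression matrix; apply a missing-value policy first")
  }
  bad <- !is.finite(x) & !is.na(x)
  if (any(bad)) {
    stop(
      "non-finite entries in expression matrix (first at gene '",
      rownames(x)[which(bad, arr.ind = TRUE)[1, 1]], "')"
    )
  }
  invisible(x)
}

#' Read a gene-expression matrix from delimited text
#'
#' Tab-separated by default; comma-separated files are auto-detected from
#' the header line. The first column holds gene ids, the header row sample
#' ids.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  sep <- if (n_com > n_tab) "," else "\t"
  df <- utils::read.table(path,
    header = TRUE, sep = sep, row.names = 1L,
    check.names = FALSE, comment.char = "", quote = ""
  )
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  validate_expression(x, allow_missing = TRUE)
  x
}

#' Write a gene-expression matrix (or any labeled numeric matrix) as TSV
#'
#' Mirrors [read_expression()]: gene ids in the first column, sample ids in
#' the header. `read_expression(write_expression(x, f))` reproduces `x` to
#' full double precision.
#'
#' @param x numeric matrix with dimnames.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  write_tsv_matrix(x, path)
  invisible(path)
}

# shared TSV writer: leading empty header cell, row labels in column 1,
# numbers at full precision so round-trips are lossless
write_tsv_matrix <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v) paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Remove outlier samples by standardized network connectivity
#'
#' Builds the sample-sample Pearson-correlation adjacency, sums it per
#' sample (excluding the self term) to obtain a network connectivity, and
#' z-scores connectivities across samples. Samples whose standardized
#' connectivity falls below `z_cut` are dropped — the usual expression-QC
#' rule for flagging individuals that correlate poorly with the rest of the
#' cohort.
#'
#' @param x numeric matrix, genes x samples.
#' @param z_cut negative real; default -2.5.
#' @return list with `x` (the filtered matrix, original sample order
#'   preserved) and `removed` (character vector of dropped sample ids).
#' @export
remove_outlier_samples <- function(x, z_cut = -2.5) {
  validate_expression(x)
  if (!is.numeric(z_cut) || length(z_cut) != 1L || !is.finite(z_cut) || z_cut >= 0) {
    stop("z_cut must be a single negative number")
  }
  # a sample constant across genes has no defined correlation with anything
  const_sample <- apply(x, 2L, function(v) pop_sd(v) == 0)
  if (any(const_sample)) {
    stop("constant sample(s), correlation undefined: ",
         paste(colnames(x)[const_sample], collapse = ", "))
  }
  cc <- stats::cor(x)
  k <- rowSums(cc) - 1
  s <- stats::sd(k)
  z <- if (is.na(s) || s == 0) rep(0, length(k)) else (k - mean(k)) / s
  drop <- z < z_cut
  if (sum(!drop) < 3L) {
    stop("outlier removal would leave fewer than 3 samples; loosen z_cut")
  }
  list(
    x = x[, !drop, drop = FALSE],
    removed = colnames(x)[drop],
    connectivity_z = stats::setNames(z, colnames(x))
  )
}

#' Centre and standardize each gene across samples
#'
#' Every gene row is shifted to mean 0 and scaled to standard deviation 1.
#' The population standard deviation (divide by n) is used; this choice is
#' documented and tested so it stays auditable. Standardization is strictly
#' row-wise: column (sample) means are not touched.
#'
#' @param x numeric matrix, genes x samples.
#' @param impute_missing logical; if `TRUE`, `NA` entries are replaced by the
#'   gene's mean over observed samples before standardizing. If `FALSE`
#'   (default) any missing value is an error.
#' @param drop_zero_variance logical; if `TRUE`, constant genes are dropped
#'   with a warning instead of raising an error.
#' @return numeric matrix of the same shape (minus dropped genes) and labels.
#' @export
normalize_expression <- function(x, impute_missing = FALSE, drop_zero_variance = FALSE) {
  validate_expression(x, allow_missing = impute_missing)
  if (anyNA(x)) {
    if (!impute_missing) stop("missing values present; set impute_missing = TRUE to mean-impute per gene")
    for (i in which(rowSums(is.na(x)) > 0L)) {
      v <- x[i, ]
      if (all(is.na(v))) stop("gene '", rownames(x)[i], "' is entirely missing")
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      x[i, ] <- v
    }
  }
  s <- row_pop_sd(x)
  zero <- s == 0
  if (any(zero)) {
    if (drop_zero_variance) {
      warning("dropping ", sum(zero), " zero-variance gene(s): ",
              paste(utils::head(rownames(x)[zero], 5L), collapse = ", "),
              if (sum(zero) > 5L) ", ..." else "")
      x <- x[!zero, , drop = FALSE]
      s <- s[!zero]
      if (nrow(x) < 2L) stop("fewer than 2 genes remain after dropping constant genes")
    } else {
      stop("zero variance gene '", rownames(x)[which(zero)[1L]],
           "'; drop constant genes first (drop_zero_variance = TRUE)")
    }
  }
  (x - rowMeans(x)) / s
}
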