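# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

row_pop_sd <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans((x - m)^2))
}

#' Optimal one-to-one matching between two sets by a score matrix
#'
#' Finds the assignment of rows to distinct columns maximizing the total
#' score. Exact (exhaustive) for small problems, greedy otherwise. Used by
#' the component- and module-matching utilities to resolve the permutation
#' ambiguity inherent to matrix decompositions.
#'
#' @param score numeric matrix; `nrow(score)` must not exceed `ncol(score)`.
#' @return integer vector of length `nrow(score)`: the column assigned to
#'   each row.
#' @keywords internal
best_assignment <- function(score) {
  n <- nrow(score)
  m <- ncol(score)
  if (n > m) stop("score matrix must have nrow <= ncol")
  if (n <= 7L && m <= 8L) {
    best <- -Inf
    best_sel <- integer(n)
    sel <- integer(n)
    used <- logical(m)
    rec <- function(i, acc) {
      if (i > n) {
        if (acc > best) {
          best <<- acc
          best_sel <<- sel
        }
        return(invisible(NULL))
      }
      for (j in seq_len(m)) {
        if (!used[j]) {
          used[j] <<- TRUE
          sel[i] <<- j
          rec(i + 1L, acc + score[i, j])
          used[j] <<- FALSE
        }
      }
    }
    rec(1L, 0)
    return(best_sel)
  }
  # greedy: repeatedly take the largest remaining score
  sel <- integer(n)
  row_open <- rep(TRUE, n)
  col_open <- rep(TRUE, m)
  for (step in seq_len(n)) {
    sub <- score
    sub[!row_open, ] <- -Inf
    sub[, !col_open] <- -Inf
    ij <- arrayInd(which.max(sub), dim(sub))
    sel[ij[1]] <- ij[2]
    row_open[ij[1]] <- FALSE
    col_open[ij[2]] <- FALSE
  }
  sel
}

#' Match estimated components to planted components
#'
#' Decompositions recover components only up to permutation and sign.
#' This utility pairs each planted (reference) component with the estimated
#' component maximizing total |Pearson r|, one-to-one.
#'
#' @param estimated numeric matrix, items x k_est (e.g. signatures over genes).
#' @param planted numeric matrix, items x k_true, same rows as `estimated`.
#' @return data.frame with one row per planted component: `planted`,
#'   `estimated` (matched column index), `r` (signed Pearson correlation of
#'   the matched pair) and `abs_r`.
#' @export
match_components <- function(estimated, planted) {
  estimated <- as.matrix(estimated)
  planted <- as.matrix(planted)
  if (nrow(estimated) != nrow(planted)) {
    stop("estimated and planted must be over the same items (rows)")
  }
  if (ncol(planted) > ncol(estimated)) {
    stop("need at least as many estimated components as planted ones")
  }
  r <- stats::cor(planted, estimated)
  sel <- best_assignment(abs(r))
  data.frame(
    planted = seq_len(ncol(planted)),
    estimated = sel,
    r = r[cbind(seq_len(ncol(planted)), sel)],
    abs_r = abs(r[cbind(seq_len(ncol(planted)), sel)])
  )
}

#' Match detected modules to planted modules by Jaccard similarity
#'
#' @param detected logical membership matrix, genes x modules.
#' @param planted logical membership matrix, genes x modules (reference).
#' @return data.frame with one row per planted module: `planted`, `detected`
#'   (matched column) and `jaccard`.
#' @export
match_modules <- function(detected, planted) {
  detected <- as.matrix(detected)
  planted <- as.matrix(planted)
  if (nrow(detected) != nrow(planted)) {
    stop("membership matrices must be over the same genes (rows)")
  }
  if (ncol(planted) > ncol(detected)) {
    stop("need at least as many detected modules as planted ones")
  }
  jac <- matrix(0, ncol(planted), ncol(detected))
  for (i in seq_len(ncol(planted))) {
    for (j in seq_len(ncol(detected))) {
      inter <- sum(planted[, i] & detected[, j])
      uni <- sum(planted[, i] | detected[, j])
      jac[i, j] <- if (uni == 0) 0 else inter / uni
    }
  }
  sel <- best_assignment(jac)
  data.frame(
    planted = seq_len(ncol(planted)),
    detected = sel,
    jaccard = jac[cbind(seq_len(ncol(planted)), sel)]
  )
}
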