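# End-to-end orchestration: preprocess -> (select k / method) -> decompose
# -> kurtosis filter -> module assignment -> hub genes -> trait association,
# with format-stable TSV/JSON writers and a run manifest.

#' Run the full overlapping-module pipeline
#'
#' Executes every stage in order on a raw expression matrix. With
#' `method = "auto"` or `k = "auto"` the permutation parallel analysis is
#' run first and its chosen component count (and recommended backend) used;
#' explicit values bypass it. All randomness derives from `seed`, so a
#' rerun with identical inputs and configuration reproduces every output
#' byte for byte.
#'
#' @param x numeric matrix, genes x samples (raw scale; the pipeline
#'   normalizes internally), or a path readable by [read_expression()].
#' @param clinical optional data.frame of numeric features with sample ids
#'   as rownames; when supplied, module-trait associations are computed.
#' @param method `"auto"`, `"ICA"` or `"IPCA"`.
#' @param k `"auto"` or an explicit positive integer.
#' @param assign `"FDR"` or `"Zscore"` (z-score assignment pairs only with
#'   ICA).
#' @param q tail-FDR assignment threshold; default 0.001.
#' @param k_sigma z-score assignment threshold; default 3.
#' @param kurtosis_threshold signature retention cut; default 3.
#' @param remove_outliers logical; run the connectivity-based sample QC
#'   (default TRUE).
#' @param z_cut outlier cut on standardized connectivity; default -2.5.
#' @param impute_missing passed to [normalize_expression()].
#' @param B,sig_level permutation count and significance level for the
#'   component selection; defaults 50 and 0.05.
#' @param n_hub hub genes reported per module; default 10.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir optional directory; when given, every stage's tables plus
#'   a `manifest.json` are written there.
#' @return object of class `"ocmod_run"`: list with `x_norm`,
#'   `removed_samples`, `selection` (or NULL), `decomposition`, `filter`,
#'   `modules`, `hubs`, `association` (or NULL), `config`, `warnings`.
#' @export
run_pipeline <- function(x, clinical = NULL,
                         method = c("auto", "ICA", "IPCA"), k = "auto",
                         assign = c("FDR", "Zscore"),
                         q = 0.001, k_sigma = 3, kurtosis_threshold = 3,
                         remove_outliers = TRUE, z_cut = -2.5,
                         impute_missing = FALSE,
                         B = 50L, sig_level = 0.05,
                         n_hub = 10L, seed = 1L, out_dir = NULL) {
  method <- match.arg(method)
  assign <- match.arg(assign)
  if (method == "IPCA" && assign == "Zscore") {
    stop("z-score assignment pairs only with ICA; IPCA uses the tail-FDR assigner")
  }
  if (is.character(x) && length(x) == 1L) x <- read_expression(x)
  validate_expression(x, allow_missing = impute_missing)
  k_auto <- identical(k, "auto")
  if (!k_auto) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("k must be 'auto' or a positive integer")
  }

  warn_log <- character(0)
  note <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, paste0("[", stage, "] ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  removed <- character(0)
  if (remove_outliers) {
    qc <- note("preprocess", remove_outlier_samples(x, z_cut = z_cut))
    x <- qc$x
    removed <- qc$removed
  }
  xn <- note("preprocess", normalize_expression(x, impute_missing = impute_missing,
                                                drop_zero_variance = TRUE))

  selection <- NULL
  if (k_auto || method == "auto") {
    selection <- note("select", select_components(
      xn, B = B, alpha = sig_level, seed = seed, recommend = (method == "auto")
    ))
    if (k_auto) k <- selection$chosen_k
    if (k < 1L) {
      stop("component selection found no non-random structure (chosen k = 0); ",
           "nothing to decompose")
    }
    if (method == "auto") method <- selection$recommended_method
  }

  decomp <- note("decompose", decompose_expression(xn, method = method, k = k, seed = seed))
  filt <- note("filter", filter_signatures(decomp, threshold = kurtosis_threshold))
  detect_method <- if (assign == "Zscore") "ICA-Zscore" else paste0(method, "-FDR")
  thr <- if (assign == "Zscore") k_sigma else q
  modules <- note("detect", detect_modules(decomp, filt, method = detect_method, threshold = thr))
  hubs <- note("hubs", top_hub_genes(modules, n_hub = n_hub))

  assoc <- NULL
  if (!is.null(clinical)) {
    assoc <- note("associate", module_trait_correlation(modules, clinical))
  }

  config <- list(
    method = method, k = k, assign = assign, q = q, k_sigma = k_sigma,
    kurtosis_threshold = kurtosis_threshold, remove_outliers = remove_outliers,
    z_cut = z_cut, B = as.integer(B), sig_level = sig_level,
    n_hub = as.integer(n_hub), seed = as.integer(seed)
  )
  run <- structure(
    list(
      x_norm = xn, removed_samples = removed, selection = selection,
      decomposition = decomp, filter = filt, modules = modules,
      hubs = hubs, association = assoc, config = config,
      warnings = warn_log
    ),
    class = "ocmod_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ocmod_run <- function(x, ...) {
  cat("Overlapping-module run\n")
  cat(sprintf("  method = %s, k = %d, assigner = %s (threshold %g), seed = %d\n",
              x$config$method, x$config$k, x$config$assign,
              if (x$config$assign == "Zscore") x$config$k_sigma else x$config$q,
              x$config$seed))
  if (length(x$removed_samples) > 0L) {
    cat("  removed outlier samples: ", paste(x$removed_samples, collapse = ", "), "\n", sep = "")
  }
  print(x$modules)
  if (length(x$warnings) > 0L) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Write every artifact of a pipeline run
#'
#' Emits the stage outputs as labeled TSV files plus `manifest.json`
#' recording the configuration, package version, seed, per-stage warnings
#' and the list of written files. File contents are deterministic given
#' the run, so identical reruns produce byte-identical output.
#'
#' @param run `"ocmod_run"` object.
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "ocmod_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    normalized = file.path(dir, "expression_normalized.tsv")
  )
  write_tsv_matrix(run$x_norm, paths[["normalized"]])

  if (!is.null(run$selection)) {
    paths[["selection"]] <- file.path(dir, "component_selection.tsv")
    utils::write.table(as.data.frame(run$selection), paths[["selection"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths[["selection_summary"]] <- file.path(dir, "component_selection.json")
    jsonlite::write_json(
      list(chosen_k = run$selection$chosen_k,
           recommended_method = run$selection$recommended_method),
      paths[["selection_summary"]], auto_unbox = TRUE, digits = NA
    )
  }

  dpaths <- write_decomposition(run$decomposition, dir)
  paths[c("signatures", "patterns", "decomposition_config")] <- dpaths

  paths[["kurtosis"]] <- file.path(dir, "kurtosis_filter.tsv")
  utils::write.table(
    data.frame(
      signature = seq_along(run$filter$kurtosis_values),
      kurtosis = run$filter$kurtosis_values,
      kept = seq_along(run$filter$kurtosis_values) %in% run$filter$kept
    ),
    paths[["kurtosis"]], sep = "\t", quote = FALSE, row.names = FALSE
  )

  mpaths <- write_modules(run$modules, dir)
  paths[c("membership", "modules_long")] <- mpaths

  paths[["hubs"]] <- file.path(dir, "hub_genes.tsv")
  utils::write.table(run$hubs, paths[["hubs"]], sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(run$association)) {
    for (nm in c("r", "p", "p_adj", "n_used")) {
      key <- paste0("association_", nm)
      paths[[key]] <- file.path(dir, paste0(key, ".tsv"))
      write_tsv_matrix(run$association[[nm]], paths[[key]])
    }
  }

  paths[["manifest"]] <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(
      package = "ocmod",
      version = as.character(utils::packageVersion("ocmod")),
      config = run$config,
      removed_samples = run$removed_samples,
      module_ids = run$modules$module_ids,
      module_sizes = unname(colSums(run$modules$membership)),
      converged = run$decomposition$converged,
      warnings = run$warnings,
      files = basename(unname(paths[names(paths) != "manifest"]))
    ),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
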