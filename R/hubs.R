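# Hub-gene ranking: genes at the extremes of a module's signature
# distribution are taken as the module's most influential members.

#' Top hub genes per module
#'
#' Within each module, member genes are ranked by descending absolute
#' signature weight — both tails of the distribution are eligible — with
#' ties broken by gene id so the report is deterministic. The top
#' `min(n_hub, module size)` genes are returned per module.
#'
#' @param m `"module_set"` object.
#' @param n_hub number of hub genes to report per module; default 10.
#' @return data.frame of class `"hub_report"` with columns `module`,
#'   `rank`, `gene`, `weight`.
#' @export
top_hub_genes <- function(m, n_hub = 10L) {
  stopifnot(inherits(m, "module_set"))
  n_hub <- as.integer(n_hub)
  if (is.na(n_hub) || n_hub < 1L) stop("n_hub must be at least 1")
  rows <- lapply(m$module_ids, function(id) {
    members <- rownames(m$membership)[m$membership[, id]]
    w <- m$weights[members, id]
    o <- order(-abs(w), members)
    take <- utils::head(o, n_hub)
    data.frame(
      module = id,
      rank = seq_along(take),
      gene = members[take],
      weight = unname(w[take])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hub_report", "data.frame")
  attr(out, "n_hub") <- n_hub
  out
}
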