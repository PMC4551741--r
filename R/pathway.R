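#' Aggregate per-gene BMD results to gene-set summaries
#'
#' For every gene set, the modeled member genes (status `"modeled"`; genes
#' excluded above the top dose or unmodeled do not contribute) are
#' intersected case-insensitively with the set, and the arithmetic mean and
#' median of their BMDs and BMDLs are reported for sets with at least
#' `min_genes` modeled members. Genes with a BMD but no BMDL contribute to
#' the BMD statistics only; the BMDL gene count is reported separately.
#'
#' @param results a `bmd_result` data frame from [run_gene_bmd()].
#' @param sets a [gene_set_collection()].
#' @param min_genes minimum modeled members (default 3).
#' @return data frame of class `pathway_bmd_summary`, sorted by `bmd_mean`
#'   ascending: `set_name`, `n_genes_modeled`, `n_genes_bmdl`, `bmd_mean`,
#'   `bmd_median`, `bmdl_mean`, `bmdl_median`. The per-set gene-level
#'   values are kept in the `"gene_values"` attribute for audit.
#' @export
aggregate_pathways <- function(results, sets, min_genes = 3L) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (nrow(results) == 0L) stop("empty BMD result table")
  modeled <- results[results$status == "modeled" & is.finite(results$bmd), ]
  key <- toupper(modeled$gene)
  rows <- list(); audit <- list()
  for (nm in names(sets)) {
    members <- toupper(sets[[nm]])
    idx <- which(key %in% members)
    if (length(idx) < min_genes) next
    sub <- modeled[idx, ]
    bmdl <- sub$bmdl[is.finite(sub$bmdl)]
    rows[[nm]] <- data.frame(
      set_name = nm,
      n_genes_modeled = nrow(sub),
      n_genes_bmdl = length(bmdl),
      bmd_mean = mean(sub$bmd),
      bmd_median = stats::median(sub$bmd),
      bmdl_mean = if (length(bmdl)) mean(bmdl) else NA_real_,
      bmdl_median = if (length(bmdl)) stats::median(bmdl) else NA_real_,
      stringsAsFactors = FALSE)
    audit[[nm]] <- sub[, c("gene", "model", "bmd", "bmdl")]
  }
  if (length(rows) == 0L) {
    out <- data.frame(set_name = character(), n_genes_modeled = integer(),
                      n_genes_bmdl = integer(), bmd_mean = numeric(),
                      bmd_median = numeric(), bmdl_mean = numeric(),
                      bmdl_median = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$bmd_mean, out$set_name), ]
  }
  rownames(out) <- NULL
  attr(out, "gene_values") <- audit
  class(out) <- c("pathway_bmd_summary", "data.frame")
  out
}

#' @export
print.pathway_bmd_summary <- function(x, ...) {
  cat(sprintf("pathway_bmd_summary: %d sets\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 15L), digits = 4)
  if (nrow(x) > 15L) cat("...\n")
  invisible(x)
}
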