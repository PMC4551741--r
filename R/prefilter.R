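#' Present calls for count data (cpm rule)
#'
#' A gene is called present when at least `min_samples` samples *within a
#' single dose group* reach `cpm_threshold` counts per million (inclusive).
#' This is the sequencing analogue of a detection filter: a transcript must
#' be reliably observed in at least one experimental group to be modeled.
#'
#' @param dset a [dose_response_set()] on the `counts` scale.
#' @param cpm_threshold counts-per-million cut (default 0.5).
#' @param min_samples samples per group that must pass (default 3).
#' @return named logical vector, one flag per gene.
#' @export
present_call_counts <- function(dset, cpm_threshold = 0.5, min_samples = 3L) {
  stopifnot(inherits(dset, "dose_response_set"))
  if (dset$value_scale != "counts")
    stop("present_call_counts requires a counts-scale dataset")
  lib <- colSums(dset$values)
  if (any(lib <= 0)) stop("every sample must have positive total counts")
  cpm <- sweep(dset$values, 2L, lib, "/") * 1e6
  pass <- cpm >= cpm_threshold
  groups <- factor(dset$doses)
  per_group <- vapply(levels(groups), function(g)
    rowSums(pass[, groups == g, drop = FALSE]) >= min_samples,
    logical(nrow(pass)))
  out <- apply(per_group, 1L, any)
  names(out) <- rownames(dset$values)
  out
}

#' Present calls for intensity data (background + k*SD rule)
#'
#' A gene is present when its signal reaches
#' `background_mean + multiplier * background_sd` (inclusive) in all but one
#' sample of at least one dose group — the same "all but one" quorum as the
#' counts rule. Background statistics come from non-target control features
#' and are supplied on the same scale as the stored values.
#'
#' @param dset a [dose_response_set()] on the `log2_intensity` scale.
#' @param background_mean,background_sd background signal statistics.
#' @param multiplier number of background SDs above the mean (default 3).
#' @return named logical vector, one flag per gene.
#' @export
present_call_intensity <- function(dset, background_mean, background_sd,
                                   multiplier = 3) {
  stopifnot(inherits(dset, "dose_response_set"))
  if (background_sd < 0) stop("background_sd must be non-negative")
  thr <- background_mean + multiplier * background_sd
  pass <- dset$values >= thr
  groups <- factor(dset$doses)
  per_group <- vapply(levels(groups), function(g) {
    sub <- pass[, groups == g, drop = FALSE]
    rowSums(sub) >= ncol(sub) - 1L
  }, logical(nrow(pass)))
  out <- apply(per_group, 1L, any)
  names(out) <- rownames(dset$values)
  out
}

# vectorised one-way ANOVA decomposition over a gene x sample matrix;
# returns list(ss_within, ss_between, group_means, df1, df2, n_total)
.anova_decomp <- function(mat, doses) {
  groups <- factor(doses)
  n_g <- as.vector(table(groups))
  if (any(n_g < 2L)) stop("every dose group needs at least 2 samples for ANOVA")
  G <- stats::model.matrix(~ 0 + groups)              # samples x groups
  sums <- mat %*% G
  means <- sweep(sums, 2L, n_g, "/")
  grand <- rowMeans(mat)
  ss_between <- rowSums(sweep((means - grand)^2, 2L, n_g, "*"))
  fitted <- means[, as.integer(groups), drop = FALSE]
  ss_within <- rowSums((mat - fitted)^2)
  list(ss_within = ss_within, ss_between = ss_between,
       group_means = means, n_g = n_g,
       df1 = nlevels(groups) - 1L, df2 = ncol(mat) - nlevels(groups))
}

#' Per-gene one-way ANOVA p-values across dose groups
#'
#' Classical fixed-effects one-way ANOVA F-test of any difference among dose
#' group means, computed on the log2 analysis scale (see
#' [analysis_matrix()]). Genes with zero between-group and zero within-group
#' variance get p = 1.
#'
#' @param dset a [dose_response_set()].
#' @return named numeric vector of p-values.
#' @export
anova_pvalues <- function(dset) {
  stopifnot(inherits(dset, "dose_response_set"))
  mat <- analysis_matrix(dset)
  d <- .anova_decomp(mat, dset$doses)
  f <- (d$ss_between / d$df1) / (d$ss_within / d$df2)
  p <- stats::pf(f, d$df1, d$df2, lower.tail = FALSE)
  degenerate <- d$ss_between < .Machine$double.eps & d$ss_within < .Machine$double.eps
  p[degenerate] <- 1
  p[is.na(p) & !degenerate] <- 1                      # 0/positive handled by pf
  names(p) <- rownames(mat)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone in rank and capped
#' at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and names.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-gene signed fold changes versus control, per dose
#'
#' On the log2 analysis scale the fold change for dose d is the group-mean
#' difference `delta = mean(d) - mean(0)`, reported with the signed
#' convention `FC = 2^delta` for up-regulation and `-2^(-delta)` for
#' down-regulation (so -2 means halving and the control column is +1). For
#' delta-Ct data this is exactly the delta-delta-Ct method: the analysis
#' scale negates Ct, so `-ddCt = delta` and the same rule applies.
#'
#' @param dset a [dose_response_set()].
#' @return numeric matrix, genes x dose levels (control column included,
#'   all +1).
#' @export
fold_changes <- function(dset) {
  stopifnot(inherits(dset, "dose_response_set"))
  mat <- analysis_matrix(dset)
  lev <- dose_levels(dset)
  if (!0 %in% lev) stop("control group (dose 0) missing")
  d <- .anova_decomp(mat, dset$doses)
  means <- d$group_means
  colnames(means) <- levels(factor(dset$doses))
  delta <- means - means[, which(colnames(means) == "0")]
  fc <- ifelse(delta >= 0, 2^delta, -2^(-delta))
  colnames(fc) <- colnames(means)
  rownames(fc) <- rownames(mat)
  fc[, as.character(lev), drop = FALSE]
}

# pooled-variance two-sample t-test p of each dose group vs control,
# vectorised over genes (classical per-comparison p for DEG bookkeeping)
.pairwise_control_p <- function(mat, doses) {
  lev <- sort(unique(doses))
  ctrl <- mat[, doses == 0, drop = FALSE]
  n0 <- ncol(ctrl); m0 <- rowMeans(ctrl)
  ss0 <- rowSums((ctrl - m0)^2)
  pos <- lev[lev > 0]
  out <- matrix(NA_real_, nrow(mat), length(pos),
                dimnames = list(rownames(mat), as.character(pos)))
  for (j in seq_along(pos)) {
    g <- mat[, doses == pos[j], drop = FALSE]
    n1 <- ncol(g); m1 <- rowMeans(g)
    ss1 <- rowSums((g - m1)^2)
    df <- n0 + n1 - 2L
    sp2 <- (ss0 + ss1) / df
    tt <- (m1 - m0) / sqrt(sp2 * (1 / n0 + 1 / n1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    deg <- sp2 < .Machine$double.eps
    p[deg] <- ifelse(abs(m1 - m0)[deg] < .Machine$double.eps, 1, 0)
    out[, j] <- p
  }
  out
}

#' Per-gene filter statistics
#'
#' Computes, for every present gene, the omnibus one-way ANOVA p, its
#' BH-adjusted value (across the present genes), signed fold changes per
#' dose and classical pooled-t per-comparison p-values versus control.
#'
#' @param dset a [dose_response_set()].
#' @param present optional logical vector (as from [present_call_counts()]
#'   or [present_call_intensity()]); defaults to all genes present.
#' @return object of class `gene_stats`: a list with `table` (data frame:
#'   gene, present, anova_p, fdr_p, max_abs_fc), `fold_changes` and
#'   `pairwise_p` matrices.
#' @export
gene_stats <- function(dset, present = NULL) {
  stopifnot(inherits(dset, "dose_response_set"))
  genes <- rownames(dset$values)
  if (is.null(present)) present <- stats::setNames(rep(TRUE, length(genes)), genes)
  stopifnot(length(present) == length(genes))
  keep <- genes[present]
  sub <- dset
  sub$values <- dset$values[keep, , drop = FALSE]
  mat <- analysis_matrix(sub)
  p <- anova_pvalues(sub)
  fdr <- bh_adjust(p)
  fc <- fold_changes(sub)
  pw <- .pairwise_control_p(mat, sub$doses)
  tab <- data.frame(gene = keep,
                    anova_p = unname(p), fdr_p = unname(fdr),
                    max_abs_fc = apply(abs(fc[, colnames(fc) != "0",
                                              drop = FALSE]), 1L, max),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fold_changes = fc, pairwise_p = pw,
                 present = present),
            class = "gene_stats")
}

#' @export
print.gene_stats <- function(x, ...) {
  cat(sprintf("gene_stats: %d present genes (of %d); %d with ANOVA p < 0.05, %d with FDR p < 0.05\n",
              nrow(x$table), length(x$present),
              sum(x$table$anova_p < 0.05), sum(x$table$fdr_p < 0.05)))
  invisible(x)
}

#' Gene lists for the three pre-filter tiers, plus the DEG list
#'
#' Tier `none` keeps every present gene; tier `anova` requires the omnibus
#' ANOVA p below `alpha`; tier `fdr` requires the BH-adjusted p below
#' `alpha`. The DEG list additionally requires an absolute signed fold
#' change of at least `fc_threshold` in some dose. Lists are nested:
#' `fdr` is a subset of `anova`, which is a subset of `none`.
#'
#' @param stats a [gene_stats()] object.
#' @param alpha significance level (default 0.05).
#' @param fc_threshold DEG fold-change cut (default 1.5).
#' @return list with character vectors `none`, `anova`, `fdr`, `deg`.
#' @export
select_genes <- function(stats, alpha = 0.05, fc_threshold = 1.5) {
  stopifnot(inherits(stats, "gene_stats"))
  tab <- stats$table
  list(none = tab$gene,
       anova = tab$gene[tab$anova_p < alpha],
       fdr = tab$gene[tab$fdr_p < alpha],
       deg = tab$gene[tab$fdr_p < alpha & tab$max_abs_fc >= fc_threshold])
}
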