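#' Cross-platform fold-change regression
#'
#' Ordinary least squares of platform B on platform A log2 effects over a
#' stated gene universe (typically the union of DEGs from the two
#' platforms, restricted to genes measured on both). Signed fold changes
#' are mapped back to log2 differences before regression to avoid the
#' discontinuity of the signed scale at +/-1.
#'
#' @param fc_a,fc_b named vectors of signed fold changes (one dose's
#'   per-gene values from [fold_changes()]).
#' @param universe gene symbols over which to regress; defaults to the
#'   genes shared by `fc_a` and `fc_b`.
#' @return list: `r_squared`, `slope`, `intercept`, `p` (two-sided slope
#'   test), `n_genes`.
#' @export
fc_regression <- function(fc_a, fc_b, universe = NULL) {
  if (is.null(universe)) universe <- intersect(names(fc_a), names(fc_b))
  universe <- intersect(intersect(universe, names(fc_a)), names(fc_b))
  if (length(universe) < 3L)
    stop("fewer than 3 shared genes in the regression universe")
  to_log2 <- function(fc) sign(fc) * log2(abs(fc))   # |fc| >= 1 by convention
  x <- to_log2(fc_a[universe]); y <- to_log2(fc_b[universe])
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p = unname(sm$coefficients[2L, 4L]),
       n_genes = length(universe))
}

#' Pairwise and overall overlap of gene (or pathway) lists
#'
#' Exact intersection cardinalities by unique, case-normalized symbol, with
#' Jaccard indices for every pair and the size of the intersection across
#' all lists.
#'
#' @param lists_by_platform named list of character vectors.
#' @return list: `sizes` (unique symbols per list), `pairwise` (data frame
#'   with `a`, `b`, `intersection`, `union`, `jaccard`), `common_all`
#'   (count in every list).
#' @export
overlap_stats <- function(lists_by_platform) {
  if (length(lists_by_platform) < 2L) stop("at least 2 lists are required")
  lists <- lapply(lists_by_platform, function(x) unique(toupper(x)))
  nms <- names(lists)
  pairs <- utils::combn(nms, 2L)
  pw <- apply(pairs, 2L, function(pr) {
    i <- length(intersect(lists[[pr[1L]]], lists[[pr[2L]]]))
    u <- length(union(lists[[pr[1L]]], lists[[pr[2L]]]))
    data.frame(a = pr[1L], b = pr[2L], intersection = i, union = u,
               jaccard = if (u == 0L) 0 else i / u,
               stringsAsFactors = FALSE)
  })
  list(sizes = lengths(lists),
       pairwise = do.call(rbind, pw),
       common_all = length(Reduce(intersect, lists)))
}

#' Percent of BMD values inside the apical PoD range
#'
#' The fraction (as a percentage) of BMDs falling within the window bounded
#' by the apical cancer endpoints' BMDs, both ends inclusive.
#'
#' @param bmds numeric vector of BMDs (mkd).
#' @param low,high window bounds (defaults 2.6 and 5.13 mkd).
#' @return percentage in \[0, 100\].
#' @export
percent_in_pod_range <- function(bmds, low = 2.6, high = 5.13) {
  bmds <- bmds[is.finite(bmds)]
  if (length(bmds) == 0L) stop("no finite BMD values")
  100 * mean(bmds >= low & bmds <= high)
}

#' Welch test for a filtering-induced shift in BMD distributions
#'
#' Two-sided Welch (unequal-variance) t-test between two BMD collections,
#' e.g. the filtered and unfiltered gene BMDs of one platform.
#'
#' @param values_a,values_b numeric vectors with at least 3 values each.
#' @return two-sided p-value.
#' @export
filtering_shift_test <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("each BMD collection needs at least 3 values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b)))) return(1)
    stop("degenerate zero-variance collections with different means")
  }
  stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
}
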