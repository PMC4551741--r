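#' Point of departure: the most sensitive pathway
#'
#' Approach 1: among pathways with at least `min_genes_pod` modeled genes,
#' report the one with the lowest BMD mean (and its BMDL mean). Ties go to
#' the pathway with more modeled genes, then to name order.
#'
#' @param summaries a `pathway_bmd_summary` from [aggregate_pathways()].
#' @param min_genes_pod eligibility threshold (default 4).
#' @return one-row data frame of class `pod_report`: `approach`, `pod_bmd`,
#'   `pod_bmdl`, `set_name`, `n_pathways_considered`.
#' @export
pod_lowest_pathway <- function(summaries, min_genes_pod = 4L) {
  elig <- summaries[summaries$n_genes_modeled >= min_genes_pod, ]
  if (nrow(elig) == 0L) stop("no pathway with at least ", min_genes_pod,
                             " modeled genes")
  ord <- order(elig$bmd_mean, -elig$n_genes_modeled, elig$set_name)
  w <- elig[ord[1L], ]
  .pod_report("lowest_pathway", w$bmd_mean, w$bmdl_mean, w$set_name,
              nrow(elig))
}

.pod_report <- function(approach, bmd, bmdl, set_name, n_considered) {
  out <- data.frame(approach = approach, pod_bmd = bmd, pod_bmdl = bmdl,
                    set_name = set_name,
                    n_pathways_considered = n_considered,
                    stringsAsFactors = FALSE)
  class(out) <- c("pod_report", "data.frame")
  out
}

#' Point of departure: lowest pathway validated on a second platform
#'
#' Approach 2: among the reference platform's eligible pathways, take the
#' lowest BMD mean whose set is also modeled (with at least `min_genes_pod`
#' genes) on at least one other platform. Cross-validation requires only
#' that the pathway be *modelable* elsewhere, not that its BMD agree.
#'
#' @param summaries_by_platform named list of `pathway_bmd_summary` objects,
#'   one per platform.
#' @param reference name of the reference platform (an element of
#'   `names(summaries_by_platform)`).
#' @param min_genes_pod eligibility threshold (default 4).
#' @return a `pod_report` row.
#' @export
pod_cross_validated <- function(summaries_by_platform, reference,
                                min_genes_pod = 4L) {
  if (length(summaries_by_platform) < 2L)
    stop("cross-validation requires summaries from at least 2 platforms")
  if (!reference %in% names(summaries_by_platform))
    stop("unknown reference platform: ", reference)
  ref <- summaries_by_platform[[reference]]
  others <- summaries_by_platform[names(summaries_by_platform) != reference]
  validated <- unique(unlist(lapply(others, function(s)
    s$set_name[s$n_genes_modeled >= min_genes_pod])))
  elig <- ref[ref$n_genes_modeled >= min_genes_pod &
                ref$set_name %in% validated, ]
  if (nrow(elig) == 0L) stop("no cross-validated pathway")
  ord <- order(elig$bmd_mean, -elig$n_genes_modeled, elig$set_name)
  w <- elig[ord[1L], ]
  .pod_report("cross_validated_lowest", w$bmd_mean, w$bmdl_mean, w$set_name,
              nrow(elig))
}

#' Point of departure: mode, mean and median of the pathway BMD distribution
#'
#' Approach 3: summary statistics of the pathway BMD-mean distribution. The
#' mode is the midpoint of the tallest bin of a fixed-width histogram on
#' log10(BMD mean), bin width `bin_width` log10 units. When two or more
#' near-tallest bins (within one count of the maximum) are separated by a
#' valley, the distribution is flagged multimodal and the lowest-dose peak
#' is reported — the most sensitive peak is the risk-relevant one.
#'
#' @param summaries a `pathway_bmd_summary`.
#' @param min_genes_pod eligibility threshold (default 4).
#' @param bin_width histogram bin width in log10 units (default 0.1).
#' @return data frame of class `pod_report` with rows
#'   `distribution_mode`, `distribution_mean`, `distribution_median`, plus
#'   a `multimodal` attribute.
#' @export
pod_distribution_summary <- function(summaries, min_genes_pod = 4L,
                                     bin_width = 0.1) {
  elig <- summaries[summaries$n_genes_modeled >= min_genes_pod, ]
  if (nrow(elig) < 5L)
    stop("at least 5 eligible pathways are needed for a distribution summary")
  v <- elig$bmd_mean
  lx <- log10(v)
  breaks <- seq(floor(min(lx) / bin_width) * bin_width,
                ceiling(max(lx) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
  peak_lvl <- max(h$counts)
  near <- which(h$counts >= peak_lvl - 1 & h$counts > 0)
  # peaks separated by a valley (a strictly lower bin between them)
  multimodal <- FALSE
  if (length(near) > 1L) {
    for (j in seq_len(length(near) - 1L)) {
      between <- h$counts[(near[j] + 1L):(near[j + 1L] - 1L)]
      if (length(between) > 0L && any(between < h$counts[near[j]] &
                                      between < h$counts[near[j + 1L]])) {
        multimodal <- TRUE
        break
      }
    }
  }
  mode_bin <- if (multimodal) near[1L] else which.max(h$counts)
  v_bmdl <- elig$bmdl_mean[is.finite(elig$bmdl_mean)]
  out <- rbind(
    .pod_report("distribution_mode", 10^h$mids[mode_bin], NA_real_,
                NA_character_, nrow(elig)),
    .pod_report("distribution_mean", mean(v),
                if (length(v_bmdl)) mean(v_bmdl) else NA_real_,
                NA_character_, nrow(elig)),
    .pod_report("distribution_median", stats::median(v),
                if (length(v_bmdl)) stats::median(v_bmdl) else NA_real_,
                NA_character_, nrow(elig)))
  attr(out, "multimodal") <- multimodal
  class(out) <- c("pod_report", "data.frame")
  out
}

#' Point of departure: a named mode-of-action pathway
#'
#' Approach 4: the BMD mean of a pre-specified, mechanistically motivated
#' pathway (e.g. an oxidative-stress response program known to drive the
#' apical effect). The set must be present among the summaries and
#' eligible; the two failure modes are reported distinctly, with near
#' matches listed for misspelled names.
#'
#' @param summaries a `pathway_bmd_summary`.
#' @param moa_set_name name of the mode-of-action pathway.
#' @param min_genes_pod eligibility threshold (default 4).
#' @return a `pod_report` row.
#' @export
pod_moa <- function(summaries, moa_set_name, min_genes_pod = 4L) {
  hit <- summaries[summaries$set_name == moa_set_name, ]
  if (nrow(hit) == 0L) {
    near <- agrep(moa_set_name, summaries$set_name, max.distance = 0.3,
                  value = TRUE)
    stop("pathway '", moa_set_name, "' not found among summaries",
         if (length(near)) paste0("; near matches: ",
                                  paste(utils::head(near, 3L), collapse = ", "))
         else "")
  }
  if (hit$n_genes_modeled < min_genes_pod)
    stop("pathway '", moa_set_name, "' has only ", hit$n_genes_modeled,
         " modeled genes (need ", min_genes_pod, ")")
  .pod_report("moa_pathway", hit$bmd_mean, hit$bmdl_mean, hit$set_name, 1L)
}

#' @export
print.pod_report <- function(x, ...) {
  print.data.frame(x, digits = 4)
  invisible(x)
}
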