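#' Pipeline run configuration
#'
#' Collects every tunable of the analysis in one validated list. Defaults
#' follow the conventions of BMDExpress-style transcriptomic BMD analysis:
#' a benchmark response of 1.349 control standard deviations (roughly a 10%
#' shift in the mean), one-sided 95% confidence for the BMDL, 10% extra risk
#' for quantal endpoints, and the 2.6-5.13 mkd hepatocellular adenoma /
#' carcinoma BMD window used to judge transcriptional points of departure.
#'
#' @param filter_tier pre-filter stringency: `"none"`, `"anova"` or `"fdr"`.
#' @param alpha significance level for the filters (default 0.05).
#' @param fc_threshold absolute signed fold-change cut for DEG calls
#'   (default 1.5; must be >= 1).
#' @param bmr_sd continuous benchmark response in control-SD units
#'   (default 1.349).
#' @param confidence one-sided confidence level for BMDL bounds
#'   (default 0.95).
#' @param max_iterations optimizer iteration cap per start (default 250).
#' @param bmr_extra_risk quantal benchmark response as extra risk
#'   (default 0.10).
#' @param min_genes_report minimum modeled genes for a pathway summary
#'   (default 3).
#' @param min_genes_pod minimum modeled genes for a pathway to support a
#'   point of departure (default 4).
#' @param pod_range_low,pod_range_high bounds (mkd) of the apical cancer
#'   BMD window (defaults 2.6 and 5.13).
#' @param seed integer seed for any stochastic step.
#' @return object of class `run_config` (a validated list).
#' @export
run_config <- function(filter_tier = c("fdr", "anova", "none"),
                       alpha = 0.05,
                       fc_threshold = 1.5,
                       bmr_sd = 1.349,
                       confidence = 0.95,
                       max_iterations = 250L,
                       bmr_extra_risk = 0.10,
                       min_genes_report = 3L,
                       min_genes_pod = 4L,
                       pod_range_low = 2.6,
                       pod_range_high = 5.13,
                       seed = 1L) {
  filter_tier <- match.arg(filter_tier)
  stopifnot(alpha > 0, alpha < 1,
            fc_threshold >= 1,
            bmr_sd > 0,
            confidence > 0, confidence < 1,
            max_iterations >= 1,
            bmr_extra_risk > 0, bmr_extra_risk < 1,
            min_genes_report >= 1, min_genes_pod >= 1,
            pod_range_low > 0, pod_range_high > pod_range_low)
  structure(list(filter_tier = filter_tier, alpha = alpha,
                 fc_threshold = fc_threshold, bmr_sd = bmr_sd,
                 confidence = confidence,
                 max_iterations = as.integer(max_iterations),
                 bmr_extra_risk = bmr_extra_risk,
                 min_genes_report = as.integer(min_genes_report),
                 min_genes_pod = as.integer(min_genes_pod),
                 pod_range_low = pod_range_low,
                 pod_range_high = pod_range_high,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or key=value text
#'
#' Any key of [run_config()] may appear; unknown keys are an error so typos
#' do not silently fall back to defaults.
#'
#' @param path path to a YAML file (or flat `key = value` lines, which are
#'   valid YAML).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %-17s %s\n", k, format(x[[k]])))
  invisible(x)
}
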