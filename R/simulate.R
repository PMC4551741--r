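#' Configuration of a synthetic dose-response study
#'
#' Describes a four-dose oral-gavage design (0/2/4/8 mkd by default) in
#' which a fraction of genes respond to dose along a Hill, power or linear
#' log2 curve, with platform-specific noise. Responder curves are anchored
#' on a true benchmark dose drawn log-uniformly: the amplitude parameter is
#' set so that the mean log2 change crosses `bmr_sd * noise_sd` exactly at
#' the drawn dose, making the true BMD available in closed form for
#' parameter-recovery checks.
#'
#' @param doses dose levels in mkd, control first (default `c(0, 2, 4, 8)`).
#' @param n_per_dose samples per dose group; `NULL` selects the platform
#'   default in [simulate_platform_study()] (5/5/4/5 for microarray-like
#'   data, 4 per group otherwise).
#' @param n_genes number of simulated genes (default 2000).
#' @param frac_responders fraction of genes with a true dose effect
#'   (default 0.2).
#' @param true_model_mix named proportions of `hill`, `power`, `linear`
#'   among responders (default equal thirds).
#' @param true_bmd_distribution log-uniform bounds, in mkd, for the true
#'   BMD of responders (default `c(1, 6)`). Together with the amplitude
#'   caps this keeps top-dose effects below about 8-fold, so that
#'   sequencing-like output stays approximately composition-stable (the
#'   pipeline assumes normalized inputs).
#' @param noise_sd residual SD on the log2 scale (default 0.25). May be 0
#'   for noise-free curves, in which case true BMDs are undefined (the
#'   benchmark response is zero SD units).
#' @param compression_factor multiplicative shrink applied to true log2
#'   effects on microarray-like output, emulating two-color signal
#'   compression (default 0.5; must be in (0, 1]).
#' @param library_size expected total counts per sample for RNA-seq-like
#'   output (default 2e6).
#' @param bmr_sd benchmark response, in control-SD units, defining the true
#'   BMD (default 1.349).
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(doses = c(0, 2, 4, 8),
                       n_per_dose = NULL,
                       n_genes = 2000L,
                       frac_responders = 0.2,
                       true_model_mix = c(hill = 1/3, power = 1/3, linear = 1/3),
                       true_bmd_distribution = c(1, 6),
                       noise_sd = 0.25,
                       compression_factor = 0.5,
                       library_size = 2e6,
                       bmr_sd = 1.349,
                       seed = 1L) {
  stopifnot(length(doses) >= 2L, doses[1L] == 0, !is.unsorted(doses),
            n_genes >= 1L,
            frac_responders >= 0, frac_responders <= 1,
            abs(sum(true_model_mix) - 1) < 1e-8,
            all(names(true_model_mix) %in% c("hill", "power", "linear")),
            length(true_bmd_distribution) == 2L,
            true_bmd_distribution[1L] > 0,
            true_bmd_distribution[1L] < true_bmd_distribution[2L],
            noise_sd >= 0,
            compression_factor > 0, compression_factor <= 1,
            library_size > 0, bmr_sd > 0)
  if (!is.null(n_per_dose)) stopifnot(length(n_per_dose) == length(doses),
                                      all(n_per_dose >= 2L))
  structure(list(doses = doses, n_per_dose = n_per_dose,
                 n_genes = as.integer(n_genes),
                 frac_responders = frac_responders,
                 true_model_mix = true_model_mix,
                 true_bmd_distribution = true_bmd_distribution,
                 noise_sd = noise_sd,
                 compression_factor = compression_factor,
                 library_size = library_size,
                 bmr_sd = bmr_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# mean log2 effect of gene curves at the given doses; truth is a per-gene
# parameter table with columns model, beta, delta, nu, k, n
.sim_effect_matrix <- function(truth, doses) {
  eff <- matrix(0, nrow(truth), length(doses))
  for (i in which(truth$responder)) {
    eff[i, ] <- switch(truth$model[i],
      linear = truth$beta[i] * doses,
      power  = truth$beta[i] * doses^truth$delta[i],
      hill   = truth$nu[i] * ifelse(doses > 0,
                 doses^truth$n[i] / (truth$k[i]^truth$n[i] + doses^truth$n[i]), 0))
  }
  eff
}

# closed-form dose at which |amplitude-scaled curve| reaches resp;
# returns NA when the curve cannot reach it
.sim_true_bmd <- function(model, resp, beta, delta, nu, k, n) {
  if (resp <= 0) return(NA_real_)
  switch(model,
    linear = resp / abs(beta),
    power  = (resp / abs(beta))^(1 / delta),
    hill   = {
      r <- resp / abs(nu)
      if (r >= 1) NA_real_ else k * (r / (1 - r))^(1 / n)
    })
}

#' Simulate one platform's dose-response study with known ground truth
#'
#' Responder genes follow the drawn model on the log2 scale. Microarray-like
#' output adds Gaussian noise to `baseline + compression_factor * effect`;
#' RNA-seq-like output draws Poisson counts around a log-normal gene mean on
#' the simulated curve (so log-cpm follows the curve with extra sampling
#' noise); qPCR-like output stores normalized delta-Ct values (`-effect`
#' plus noise, since lower Ct means more transcript). The returned ground
#' truth records, per gene, the responder flag, model, parameters and the
#' true BMD of the *emitted* platform (i.e. after compression), which is
#' `NA` for non-responders and for curves whose compressed amplitude cannot
#' reach the benchmark response.
#'
#' @param cfg a [sim_config()].
#' @param platform_tag `"rnaseq"`, `"microarray"` or `"qpcr"`.
#' @return list with elements `dset` (a [dose_response_set()]) and `truth`
#'   (data frame, one row per gene).
#' @export
simulate_platform_study <- function(cfg,
                                    platform_tag = c("rnaseq", "microarray", "qpcr")) {
  stopifnot(inherits(cfg, "sim_config"))
  platform_tag <- match.arg(platform_tag)
  set.seed(cfg$seed)
  n_per_dose <- cfg$n_per_dose
  if (is.null(n_per_dose))
    n_per_dose <- if (platform_tag == "microarray" && length(cfg$doses) == 4L)
      c(5L, 5L, 4L, 5L) else rep(4L, length(cfg$doses))
  doses_s <- rep(cfg$doses, times = n_per_dose)    # per-sample dose
  n_genes <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_resp <- round(cfg$frac_responders * n_genes)
  responder <- seq_len(n_genes) <= n_resp

  resp_amp <- cfg$bmr_sd * cfg$noise_sd            # log2 change defining the BMD
  lo <- cfg$true_bmd_distribution[1L]; hi <- cfg$true_bmd_distribution[2L]
  top <- max(cfg$doses)
  mix <- cfg$true_model_mix[c("hill", "power", "linear")]
  mix[is.na(mix)] <- 0

  truth <- data.frame(gene = genes, responder = responder,
                      model = NA_character_, direction = NA_real_,
                      beta = NA_real_, delta = NA_real_,
                      nu = NA_real_, k = NA_real_, n = NA_real_,
                      anchor_bmd = NA_real_, true_bmd = NA_real_,
                      stringsAsFactors = FALSE)
  if (n_resp > 0L) {
    truth$model[responder] <- sample(names(mix), n_resp, replace = TRUE, prob = mix)
    truth$direction[responder] <- sample(c(-1, 1), n_resp, replace = TRUE)
    truth$anchor_bmd[responder] <- exp(stats::runif(n_resp, log(lo), log(hi)))
    # amplitude anchoring: when noise_sd = 0 the benchmark response is zero
    # SD units, so anchor on a 1-log2-unit change instead and leave the true
    # BMD undefined
    amp <- if (resp_amp > 0) resp_amp else 1
    for (i in which(responder)) {
      B <- truth$anchor_bmd[i]; dir <- truth$direction[i]
      switch(truth$model[i],
        linear = truth$beta[i] <- dir * amp / B,
        power = {
          # cap the top-dose effect at ~3 log2 units (8-fold)
          dmax <- if (top > B) log(3 / amp) / log(top / B) else 3
          truth$delta[i] <- stats::runif(1, 1, max(1, min(3, dmax)))
          truth$beta[i] <- dir * amp / B^truth$delta[i]
        },
        hill = {
          truth$n[i] <- stats::runif(1, 1, 3)
          truth$k[i] <- B * 2^stats::runif(1, -1, 0.585)
          truth$nu[i] <- dir * amp * (truth$k[i]^truth$n[i] + B^truth$n[i]) / B^truth$n[i]
        })
    }
  }

  comp <- if (platform_tag == "microarray") cfg$compression_factor else 1
  eff <- .sim_effect_matrix(truth, cfg$doses)      # genes x dose levels
  eff_s <- comp * eff[, match(doses_s, cfg$doses), drop = FALSE]
  n_samp <- length(doses_s)

  if (resp_amp > 0) {
    for (i in which(responder)) {
      amp_par <- switch(truth$model[i], linear = , power = truth$beta[i],
                        hill = truth$nu[i])
      truth$true_bmd[i] <- .sim_true_bmd(truth$model[i], resp_amp,
                                         comp * amp_par, truth$delta[i],
                                         comp * amp_par, truth$k[i], truth$n[i])
    }
  }

  if (platform_tag == "microarray") {
    baseline <- stats::rnorm(n_genes, 8, 1)
    vals <- baseline + eff_s + matrix(stats::rnorm(n_genes * n_samp, 0, cfg$noise_sd),
                                      n_genes, n_samp)
    scale <- "log2_intensity"
  } else if (platform_tag == "qpcr") {
    base_ct <- stats::rnorm(n_genes, 5, 2)
    vals <- base_ct - eff_s + matrix(stats::rnorm(n_genes * n_samp, 0, cfg$noise_sd),
                                     n_genes, n_samp)
    scale <- "delta_ct"
  } else {
    base_l2 <- stats::rnorm(n_genes, 4, 2)
    w <- 2^base_l2; q <- w / sum(w)
    lam <- cfg$library_size * q * 2^eff_s
    lam <- lam * 2^matrix(stats::rnorm(n_genes * n_samp, 0, cfg$noise_sd),
                          n_genes, n_samp)
    vals <- matrix(stats::rpois(n_genes * n_samp, lam), n_genes, n_samp)
    scale <- "counts"
  }
  dimnames(vals) <- list(genes, sprintf("%s_d%g_%02d", platform_tag, doses_s,
                                        stats::ave(doses_s, doses_s, FUN = seq_along)))
  list(dset = dose_response_set(vals, doses_s, platform_tag = platform_tag,
                                value_scale = scale),
       truth = truth)
}

#' Build a quantal dataset from per-dose DEG counts
#'
#' The count of differentially expressed genes at each dose, out of the
#' total number of unique DEGs across all doses, is treated as a
#' dichotomous (affected / trials) dose-response profile. The control dose
#' carries zero affected by construction: differential expression is
#' defined relative to control.
#'
#' @param total_unique total number of unique DEGs (the denominator at every
#'   dose).
#' @param per_dose_counts DEG count per dose, parallel to `doses`; the entry
#'   for dose 0 must be 0.
#' @param doses dose levels in mkd (default `c(0, 2, 4, 8)`).
#' @return a [dichotomous_dataset()].
#' @export
simulate_deg_count_profile <- function(total_unique, per_dose_counts,
                                       doses = c(0, 2, 4, 8)) {
  stopifnot(length(per_dose_counts) == length(doses))
  if (!any(doses == 0) || per_dose_counts[doses == 0] != 0)
    stop("doses must include control (0) with a DEG count of 0")
  if (any(per_dose_counts > total_unique))
    stop("a per-dose DEG count exceeds the total unique DEG denominator")
  dichotomous_dataset(doses = doses, affected = per_dose_counts,
                      denominator = rep(total_unique, length(doses)))
}

#' Draw gene sets from a simulated study with controlled responder content
#'
#' Each set mixes responder and non-responder genes at the stated enrichment
#' so that pathway-level summaries have a known true BMD content.
#'
#' @param truth ground-truth data frame from [simulate_platform_study()].
#' @param n_sets number of sets.
#' @param genes_per_set members per set.
#' @param enrichment fraction of each set drawn from responder genes.
#' @param seed integer seed.
#' @return a [gene_set_collection()].
#' @export
make_gene_sets <- function(truth, n_sets, genes_per_set, enrichment, seed = 1L) {
  stopifnot(genes_per_set >= 1L, enrichment >= 0, enrichment <= 1)
  set.seed(seed)
  resp_pool <- truth$gene[truth$responder]
  non_pool <- truth$gene[!truth$responder]
  n_resp <- round(enrichment * genes_per_set)
  n_non <- genes_per_set - n_resp
  if (n_resp > length(resp_pool) || n_non > length(non_pool))
    stop("requested set size exceeds the available gene pool")
  sets <- lapply(seq_len(n_sets), function(i)
    sample(c(sample(resp_pool, n_resp), sample(non_pool, n_non))))
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  gene_set_collection(sets,
                      descriptions = rep(sprintf("synthetic set, enrichment %.2f",
                                                 enrichment), n_sets))
}
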