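# shared fixtures: tiny dose-response sets built in code

# gene x sample matrix with 4 dose groups of n = 2, values supplied per gene
make_tiny_dset <- function(values_by_gene,
                           doses = rep(c(0, 2, 4, 8), each = 2),
                           platform = "microarray",
                           scale = "log2_intensity") {
  m <- do.call(rbind, values_by_gene)
  rownames(m) <- names(values_by_gene)
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  dose_response_set(m, doses, platform_tag = platform, value_scale = scale)
}

# write an expression matrix file with a dose header row
write_matrix_file <- function(genes, values, doses, path = tempfile(fileext = ".tsv")) {
  samples <- paste0("S", seq_along(doses))
  lines <- c(paste(c("gene", samples), collapse = "\t"),
             paste(c("dose", doses), collapse = "\t"),
             vapply(seq_along(genes), function(i)
               paste(c(genes[i], values[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  path
}

# hand-built continuous fit object (for closed-form BMD checks)
make_cont_fit <- function(model_name, params, sigma_hat, du = c(0, 2, 4, 8)) {
  structure(list(model_name = model_name, params = params,
                 sigma_hat = sigma_hat, converged = TRUE,
                 ss = list(du = du, G = length(du))),
            class = "continuous_fit")
}

# hand-built dichotomous fit object
make_dich_fit <- function(model_name, params, aic = 0, gof_p = 1) {
  structure(list(model_name = model_name, params = params,
                 aic = aic, gof_p = gof_p,
                 n_params = length(params), converged = TRUE),
            class = "dichotomous_fit")
}
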