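#' Construct a dose-coded expression set
#'
#' A `dose_response_set` bundles a gene x sample expression matrix with the
#' dose (mg/kg bodyweight/day, "mkd") administered to each sample and a tag
#' for the platform that produced it. It is the universal input of the
#' pipeline: pre-filtering, fold changes and per-gene BMD modeling all
#' consume it.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are gene symbols, column names sample identifiers.
#' @param doses numeric vector of per-sample doses, parallel to the columns
#'   of `values`. Must include dose 0 (the control group) and be
#'   non-negative.
#' @param platform_tag one of `"rnaseq"`, `"microarray"`, `"qpcr"`.
#' @param value_scale one of `"log2_intensity"`, `"counts"`, `"log_cpm"`,
#'   `"delta_ct"`. `"counts"` requires non-negative integers.
#' @return an object of class `dose_response_set`.
#' @seealso [read_expression_matrix()], [analysis_matrix()]
#' @export
dose_response_set <- function(values, doses,
                              platform_tag = c("rnaseq", "microarray", "qpcr"),
                              value_scale = c("log2_intensity", "counts",
                                              "log_cpm", "delta_ct")) {
  platform_tag <- match.arg(platform_tag)
  value_scale <- match.arg(value_scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L) stop("expression matrix must contain at least one gene")
  if (is.null(rownames(values))) stop("'values' must carry gene symbols as row names")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  doses <- as.numeric(doses)
  if (length(doses) != ncol(values))
    stop("'doses' must have one entry per sample column")
  if (anyNA(doses) || anyNA(values)) stop("doses and values must not contain NA")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (!any(doses == 0)) stop("no control samples: dose 0 must be present")
  tab <- table(doses)
  if (any(tab < 2L))
    stop("every dose group needs at least 2 samples; offending dose(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (value_scale == "counts" &&
      (any(values < 0) || any(values != round(values))))
    stop("counts scale requires non-negative integer values")
  structure(list(values = values,
                 doses = doses,
                 platform_tag = platform_tag,
                 value_scale = value_scale),
            class = "dose_response_set")
}

#' @export
print.dose_response_set <- function(x, ...) {
  tab <- table(x$doses)
  cat(sprintf("dose_response_set: %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$platform_tag, x$value_scale))
  cat("  dose groups (mkd): ",
      paste(sprintf("%g (n=%d)", as.numeric(names(tab)), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dose_response_set <- function(object, ...) {
  print(object)
  cat("  value range: ", paste(signif(range(object$values), 4), collapse = " .. "),
      "\n", sep = "")
  invisible(object)
}

#' Unique, sorted dose levels of a set
#' @param dset a [dose_response_set()].
#' @return increasing numeric vector of dose levels, control first.
#' @export
dose_levels <- function(dset) sort(unique(dset$doses))

#' Expression values on the common log2 analysis scale
#'
#' Pre-filtering and continuous BMD modeling operate on a log2-like scale
#' with the convention "larger = more expressed": log2 intensities and
#' log-cpm pass through, counts are converted to log2 counts-per-million
#' with a 0.5-count prior (`log2((count + 0.5) / (libsize + 1) * 1e6)`),
#' and normalized delta-Ct values are negated (a lower Ct means more
#' transcript).
#'
#' @param dset a [dose_response_set()].
#' @return numeric matrix, same dimensions as `dset$values`.
#' @export
analysis_matrix <- function(dset) {
  v <- dset$values
  switch(dset$value_scale,
         log2_intensity = v,
         log_cpm = v,
         counts = {
           lib <- colSums(v)
           log2(sweep(v + 0.5, 2L, lib + 1, "/") * 1e6)
         },
         delta_ct = -v)
}

#' Read a tab-separated expression matrix with dose annotation
#'
#' The matrix dialect is: first column gene symbols, one column per sample,
#' a header line of sample names, and the dose of every sample supplied
#' either as a second header row whose first field starts with `dose`
#' (`dose_header_row = TRUE`) or as a two-column tab-separated sample sheet
#' (`sample`, `dose`). Duplicate gene symbols are collapsed by arithmetic
#' mean on the stored scale, with a message reporting how many rows were
#' collapsed.
#'
#' @param path path to the matrix file.
#' @param platform_tag,value_scale passed to [dose_response_set()].
#' @param dose_header_row logical; if `TRUE` the second line of the file
#'   carries the doses.
#' @param sample_sheet path to a sample sheet (header `sample<TAB>dose`);
#'   required when `dose_header_row = FALSE`.
#' @return a [dose_response_set()].
#' @export
read_expression_matrix <- function(path, platform_tag, value_scale,
                                   dose_header_row = TRUE,
                                   sample_sheet = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression matrix file is empty or header-only: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  body_start <- 2L
  doses <- NULL
  if (dose_header_row) {
    dl <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    if (!grepl("^dose", dl[[1L]], ignore.case = TRUE))
      stop("dose_header_row = TRUE but line 2 does not start with 'dose'")
    doses <- suppressWarnings(as.numeric(dl[-1L]))
    if (length(doses) != length(samples) || anyNA(doses))
      stop("dose header row does not provide a numeric dose for every sample")
    body_start <- 3L
  } else {
    if (is.null(sample_sheet))
      stop("a sample sheet is required when the matrix has no dose header row")
    sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
    if (!all(c("sample", "dose") %in% names(sheet)))
      stop("sample sheet must have columns 'sample' and 'dose'")
    idx <- match(samples, sheet$sample)
    if (anyNA(idx))
      stop("sample(s) lacking dose annotation: ",
           paste(samples[is.na(idx)], collapse = ", "))
    doses <- as.numeric(sheet$dose[idx])
  }
  fields <- strsplit(lines[body_start:length(lines)], "\t", fixed = TRUE)
  bad_len <- vapply(fields, length, 1L) != length(samples) + 1L
  if (any(bad_len))
    stop("row(s) with wrong field count at line(s): ",
         paste(which(bad_len) + body_start - 1L, collapse = ", "))
  genes <- vapply(fields, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(length(samples))))
  vals <- matrix(vals, ncol = length(samples), byrow = TRUE,
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))
    stop("non-numeric expression value(s) for gene(s): ",
         paste(utils::head(genes[bad], 5L), collapse = ", "))
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    message(sprintf("collapsed %d duplicate gene row(s) by averaging", n_dup))
  }
  dose_response_set(vals, doses, platform_tag = platform_tag,
                    value_scale = value_scale)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Duplicate members within a set are
#' dropped with a warning; duplicate set names are an error.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of gene symbols, with a
#'   `descriptions` attribute (named character vector), class
#'   `gene_set_collection`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': dropped %d duplicate member(s)",
                      f[[1L]], sum(duplicated(members))), call. = FALSE)
      members <- unique(members)
    }
    if (length(members) == 0L) stop("gene set '", f[[1L]], "' is empty")
    members
  })
  names(sets) <- nms
  gene_set_collection(sets, descriptions = vapply(fields, `[[`, "", 2L))
}

#' Build a gene-set collection from a named list
#' @param sets named list of character vectors (gene symbols).
#' @param descriptions optional character vector parallel to `sets`.
#' @return object of class `gene_set_collection` (a named list).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set name(s)")
  if (any(vapply(sets, length, 1L) == 0L)) stop("every gene set must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d..%d genes per set\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Write a results table as tab-separated text
#'
#' Numeric columns are formatted at 6 significant digits so that writing and
#' re-reading round-trips values within print precision. Column order is the
#' order of the data frame.
#'
#' @param records a non-empty data frame (any of the pipeline's result
#'   tables).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("refusing to write an empty results table")
  out <- records
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) signif(x, 6L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path path to the TSV file.
#' @return data frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
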