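# Readers and writers for the pipeline's on-disk formats: counts TSV
# (genes in rows, first column gene ID, header sample IDs), sample and gene
# annotation TSV, GMT gene-set collections, and generic result tables.
# Writers emit a deterministic column order and 12 significant digits so
# reader/writer pairs round-trip at the declared precision.

#' Construct a validated count matrix
#'
#' @param values Numeric matrix of non-negative integers, genes in rows.
#' @param gene_ids,sample_ids Unique identifier vectors matching `values`
#'   dimensions. Defaults to existing dimnames.
#' @return An integer-mode matrix with gene/sample dimnames.
#' @export
count_matrix <- function(values,
                         gene_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    gq_stop("glmqlmas_error_ids", "gene and sample identifiers are required")
  if (anyDuplicated(gene_ids))
    gq_stop("glmqlmas_error_duplicate_ids", "duplicate gene identifiers")
  if (anyDuplicated(sample_ids))
    gq_stop("glmqlmas_error_duplicate_ids", "duplicate sample identifiers")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    gq_stop("glmqlmas_error_dims", "identifier lengths do not match matrix dimensions")
  if (anyNA(values) || any(values < 0))
    gq_stop("glmqlmas_error_integrity", "counts must be non-negative and non-missing")
  if (any(values != round(values)))
    gq_stop("glmqlmas_error_integrity", "counts must be integral")
  storage.mode(values) <- "double"   # keeps totals > .Machine$integer.max safe
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' Duplicate IDs, negative, missing or non-integer entries, and ragged rows
#' each raise a distinct, named error condition.
#'
#' @param path Path to a tab-separated text file.
#' @return Validated count matrix (see [count_matrix()]).
#' @export
read_counts <- function(path) {
  if (!file.exists(path))
    gq_stop("glmqlmas_error_missing_file", paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L)
    gq_stop("glmqlmas_error_format", "empty counts file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1L]])
  if (any(lengths(fields) != ncol_expected))
    gq_stop("glmqlmas_error_ragged", "ragged rows in counts file")
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids))  # guards 1-sample edge case
  if (anyNA(vals))
    gq_stop("glmqlmas_error_integrity", "non-numeric entries in counts file")
  count_matrix(t(vals), gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write a count matrix as TSV
#' @param counts Count matrix.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  body <- apply(counts, 1L, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                              collapse = "\t"))
  writeLines(paste(rownames(counts), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated member IDs.
#' Duplicate members within a line are removed with a warning; a line with
#' fewer than three fields is an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of unique member-ID character vectors, with a
#'   `description` attribute carrying the second field per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    gq_stop("glmqlmas_error_missing_file", paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- structure(list(), names = character(0))
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    gq_stop("glmqlmas_error_format",
            paste0("GMT line ", bad[1L], " has fewer than 3 fields"))
  nms <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    if (anyDuplicated(members))
      gq_warn("duplicate members within a GMT line were deduplicated")
    unique(members)
  })
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(desc, nms)
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of member-ID vectors.
#' @param path Output path.
#' @param description Optional per-set description; defaults to set names.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id`, `alnm_status` (labels `ALNM+`, `ALNM-` or
#' the literal `NA` for missing nodal status), `prior_chemo`, `prior_radio`
#' (logical). Unknown group labels raise an error naming the offending row.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with `alnm_status` as factor
#'   `c("negative","positive","missing")`.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "alnm_status", "prior_chemo", "prior_radio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gq_stop("glmqlmas_error_format",
            paste("annotation missing columns:", paste(miss, collapse = ", ")))
  status <- df$alnm_status
  mapped <- unname(c("ALNM+" = "positive", "ALNM-" = "negative",
                     "NA" = "missing", "positive" = "positive",
                     "negative" = "negative", "missing" = "missing")[status])
  if (anyNA(mapped)) {
    row <- which(is.na(mapped))[1L]
    gq_stop("glmqlmas_error_label",
            paste0("unknown ALNM label '", status[row], "' in row ", row,
                   " (sample ", df$sample_id[row], ")"))
  }
  sample_annotation(df$sample_id, mapped,
                    prior_chemo = as.logical(df$prior_chemo),
                    prior_radio = as.logical(df$prior_radio))
}

#' Construct a validated sample annotation
#' @param sample_id Unique sample IDs.
#' @param alnm_status Character in `{"positive","negative","missing"}`.
#' @param prior_chemo,prior_radio Logical treatment flags.
#' @return Data frame of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, alnm_status,
                              prior_chemo = FALSE, prior_radio = FALSE) {
  if (anyDuplicated(sample_id))
    gq_stop("glmqlmas_error_duplicate_ids", "duplicate sample identifiers")
  ok <- alnm_status %in% c("positive", "negative", "missing")
  if (!all(ok))
    gq_stop("glmqlmas_error_label",
            paste0("unknown ALNM status '", alnm_status[!ok][1L], "'"))
  out <- data.frame(sample_id = as.character(sample_id),
                    alnm_status = factor(alnm_status,
                                         levels = c("negative", "positive", "missing")),
                    prior_chemo = rep_len(as.logical(prior_chemo), length(sample_id)),
                    prior_radio = rep_len(as.logical(prior_radio), length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_annotation", "data.frame")
  out
}

#' Write a sample annotation table as TSV
#' @param annotation Sample annotation data frame.
#' @param path Output path.
#' @export
write_sample_annotation <- function(annotation, path) {
  out <- data.frame(
    sample_id = annotation$sample_id,
    alnm_status = c(negative = "ALNM-", positive = "ALNM+",
                    missing = "NA")[as.character(annotation$alnm_status)],
    prior_chemo = annotation$prior_chemo,
    prior_radio = annotation$prior_radio)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV with fixed formatting
#'
#' Column order follows the data frame; numeric columns are written with 12
#' significant digits so a read-back is equal within formatting precision.
#'
#' @param records Data frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path Path to the TSV.
#' @return Data frame with numeric columns restored.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble a run configuration
#'
#' Central container for every tunable of the pipeline; all randomness in
#' the artifact flows from `seed`.
#'
#' @param alpha Significance level for adjusted p-values (default 0.05).
#' @param mas_M,mas_A MAS exponents on \eqn{|log2FC|} and
#'   \eqn{|log10 p_{adj}|} (defaults 1, 1).
#' @param lfc_threshold Absolute log2-fold-change gate (default 1).
#' @param resampling_R Number of balanced resampling iterations (default 500).
#' @param consistency_min Minimum same-direction significant occurrences to
#'   qualify as a biomarker (default `ceiling(resampling_R / 2)`).
#' @param seed Master seed (integer).
#' @param correction Multiple-testing correction, `"BH"` or `"bonferroni"`.
#' @return List of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, mas_M = 1, mas_A = 1, lfc_threshold = 1,
                       resampling_R = 500L,
                       consistency_min = ceiling(resampling_R / 2),
                       seed = 1L, correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(alpha > 0, alpha < 1, mas_M >= 0, mas_A >= 0, lfc_threshold >= 0,
            resampling_R >= 1, consistency_min <= resampling_R)
  structure(list(alpha = alpha, mas_M = mas_M, mas_A = mas_A,
                 lfc_threshold = lfc_threshold,
                 resampling_R = as.integer(resampling_R),
                 consistency_min = as.integer(consistency_min),
                 seed = as.integer(seed), correction = correction),
            class = "run_config")
}

#' Read a run configuration from a flat key-value YAML file
#' @param path Path to a YAML file whose top-level keys are `run_config`
#'   argument names.
#' @return `run_config` object; unknown keys are ignored with a warning.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    gq_warn(paste("ignoring unknown config keys:", paste(extra, collapse = ", ")))
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' Write a run manifest
#'
#' Records inputs, configuration, seed and package version alongside
#' outputs, for reproducibility audits.
#'
#' @param path Output JSON path.
#' @param config `run_config` object.
#' @param inputs Named character vector/list of input file paths.
#' @export
write_manifest <- function(path, config, inputs = list()) {
  manifest <- list(
    package = "glmqlmas",
    version = as.character(utils::packageVersion("glmqlmas")),
    config = unclass(config),
    inputs = as.list(inputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
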