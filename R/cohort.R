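# Cohort and gene-universe filters: drop samples with missing nodal status,
# then previously treated samples; restrict genes to protein-coding; drop
# all-zero genes before model fitting. Filters are idempotent and each
# removal is accounted for in a report.

#' Filter the cohort to untreated samples with known ALNM status
#'
#' Removal steps are applied in a fixed order — missing nodal status first,
#' then prior chemo- or radiotherapy — so the report counts are
#' reproducible.
#'
#' @param annotation A [sample_annotation()] data frame.
#' @return List with `annotation` (retained rows) and `report`, a data frame
#'   of per-step removal counts whose removals sum to input minus output.
#' @export
filter_cohort <- function(annotation) {
  if (nrow(annotation) == 0L)
    gq_stop("glmqlmas_error_empty", "empty sample annotation")
  n0 <- nrow(annotation)
  keep1 <- annotation$alnm_status != "missing"
  a1 <- annotation[keep1, , drop = FALSE]
  keep2 <- !(a1$prior_chemo | a1$prior_radio)
  a2 <- a1[keep2, , drop = FALSE]
  report <- data.frame(
    step = c("input", "missing_alnm_removed", "treated_removed", "retained"),
    n = c(n0, sum(!keep1), sum(!keep2), nrow(a2)),
    n_negative = c(sum(annotation$alnm_status == "negative"), NA, NA,
                   sum(a2$alnm_status == "negative")),
    n_positive = c(sum(annotation$alnm_status == "positive"), NA, NA,
                   sum(a2$alnm_status == "positive")))
  if (nrow(a2) == 0L) gq_warn("no samples retained after cohort filtering")
  rownames(a2) <- NULL
  list(annotation = a2, report = report)
}

#' Restrict a count matrix to protein-coding genes
#'
#' @param counts Count matrix.
#' @param genes Gene annotation data frame with `gene_id` and `biotype`;
#'   every counts row must be annotated.
#' @return Count matrix with only `protein_coding` rows, original order
#'   preserved.
#' @export
filter_protein_coding <- function(counts, genes) {
  idx <- match(rownames(counts), genes$gene_id)
  if (anyNA(idx)) {
    bad <- rownames(counts)[which(is.na(idx))[1L]]
    gq_stop("glmqlmas_error_annotation",
            paste0("gene '", bad, "' missing from annotation"))
  }
  keep <- genes$biotype[idx] == "protein_coding"
  if (!any(keep)) gq_warn("no protein-coding genes found")
  counts[keep, , drop = FALSE]
}

#' Drop genes with zero counts across all samples
#'
#' Only all-zero genes are removed (they are inestimable in the GLM); no
#' abundance-based expression filter is applied.
#'
#' @param counts Count matrix.
#' @return List with `counts` (retained rows) and `removed_ids`.
#' @export
drop_unexpressed <- function(counts) {
  keep <- rowSums(counts) > 0
  if (!any(keep)) gq_warn("all genes have zero total count")
  list(counts = counts[keep, , drop = FALSE],
       removed_ids = rownames(counts)[!keep])
}
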