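# End-to-end pipeline: cohort filtering, protein-coding restriction,
# TMM normalization, quasi-likelihood differential expression, MAS ranking
# and threshold sweep, balanced-resampling consistency, over-representation
# analysis, and separability diagnostics.

#' Run the full analysis pipeline
#'
#' @param counts Raw count matrix (all genes, all samples).
#' @param samples [sample_annotation()] covering all count columns.
#' @param genes Gene annotation data frame (`gene_id`, `biotype`).
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param config [run_config()].
#' @param resampling [resampling_config()]; `NULL` skips resampling.
#' @param diagnostics_k Component counts for the PCA sweep (default
#'   `2:20`).
#' @param lda_top_n Gene counts for LDA1 projections (default
#'   `seq(20, 100, by = 20)`).
#' @param out_dir Optional directory; when given, result tables and a run
#'   manifest are written as TSV/JSON.
#' @return List with `cohort_report`, `factors`, `de` (full `de_fit`),
#'   `ranked` (Case-1 MAS table), `sweep`, `resampling`, `biomarkers`,
#'   `intersection`, `enrichment`, `pc_metrics`, `lda`, `config`.
#' @export
run_pipeline <- function(counts, samples, genes, gene_sets = NULL,
                         config = run_config(),
                         resampling = resampling_config(
                           R = config$resampling_R,
                           min_count = config$consistency_min,
                           base_seed = config$seed),
                         diagnostics_k = 2:20,
                         lda_top_n = seq(20L, 100L, by = 20L),
                         out_dir = NULL) {
  filt <- filter_cohort(samples)
  cohort <- filt$annotation
  cm <- counts[, cohort$sample_id, drop = FALSE]
  cm <- filter_protein_coding(cm, genes)
  dz <- drop_unexpressed(cm)
  cm <- dz$counts

  de <- de_analysis(cm, cohort)
  params <- mas_params(M = config$mas_M, A = config$mas_A,
                       alpha = config$alpha,
                       lfc_threshold = config$lfc_threshold,
                       correction = if (config$correction == "BH") "BH"
                       else "bonferroni")
  ranked <- rank_and_classify(de$table, params)
  sweep_tab <- threshold_sweep(de$table, thresholds = 0:7, params = params)

  res_sum <- biomarkers <- intersection <- NULL
  if (!is.null(resampling)) {
    res_sum <- run_resampling(cm, cohort, resampling, alpha = config$alpha)
    biomarkers <- qualify(res_sum)
    intersection <- intersect_cases(ranked, biomarkers)
  }

  enrichment <- NULL
  if (!is.null(gene_sets) && length(gene_sets)) {
    universe <- intersect(rownames(cm), unique(unlist(gene_sets)))
    sig <- intersect(ranked$gene_id, universe)
    enrichment <- ora(sig, universe, gene_sets)
  }

  lc <- de$logcpm
  labels <- cohort$alnm_status == "positive"
  sel <- ranked$gene_id
  pc_metrics <- NULL
  if (length(sel) >= 2L) {
    k_ok <- diagnostics_k[diagnostics_k <= min(ncol(lc) - 1L, length(sel))]
    if (length(k_ok))
      pc_metrics <- pc_sweep(lc, lc[sel, , drop = FALSE], labels, k_ok)
  }
  lda_res <- lapply(lda_top_n[lda_top_n <= length(sel)], function(nn) {
    r <- lda1(lc[utils::head(sel, nn), , drop = FALSE], labels)
    data.frame(n = nn, separation_fraction = r$separation_fraction)
  })
  lda_tab <- if (length(lda_res)) do.call(rbind, lda_res) else NULL

  out <- list(cohort_report = filt$report, factors = de$factors, de = de,
              ranked = ranked, sweep = sweep_tab, resampling = res_sum,
              biomarkers = biomarkers, intersection = intersection,
              enrichment = enrichment, pc_metrics = pc_metrics,
              lda = lda_tab, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(filt$report, file.path(out_dir, "cohort_report.tsv"))
    write_table(de$factors, file.path(out_dir, "norm_factors.tsv"))
    write_table(de$table, file.path(out_dir, "de_table.tsv"))
    write_table(ranked, file.path(out_dir, "mas_ranked.tsv"))
    write_table(sweep_tab, file.path(out_dir, "threshold_sweep.tsv"))
    if (!is.null(biomarkers))
      write_table(biomarkers, file.path(out_dir, "biomarkers.tsv"))
    if (!is.null(enrichment))
      write_table(enrichment, file.path(out_dir, "enrichment.tsv"))
    if (!is.null(pc_metrics))
      write_table(pc_metrics, file.path(out_dir, "pc_metrics.tsv"))
    if (!is.null(lda_tab))
      write_table(lda_tab, file.path(out_dir, "lda1.tsv"))
    write_manifest(file.path(out_dir, "manifest.json"), config)
  }
  out
}
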