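# Magnitude-Altitude Score (MAS): a composite gene-ranking statistic
# combining effect size and significance,
#   MAS = |log2FC|^M * |log10(p_adj)|^A,
# with both exponents defaulting to 1 so magnitude and significance carry
# equal weight. Genes are gated by adjusted significance and an absolute
# log2FC threshold, classified up/down, and ranked by MAS.

#' MAS parameters
#' @param M,A Non-negative exponents (defaults 1, 1).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param lfc_threshold Absolute log2FC gate, strict inequality (default 1).
#' @param correction Which p-value column gates significance: `"BH"`,
#'   `"bonferroni"`, or `"raw"`.
#' @return List of class `mas_params`.
#' @export
mas_params <- function(M = 1, A = 1, alpha = 0.05, lfc_threshold = 1,
                       correction = c("BH", "bonferroni", "raw")) {
  correction <- match.arg(correction)
  stopifnot(M >= 0, A >= 0, alpha > 0, alpha < 1, lfc_threshold >= 0)
  structure(list(M = M, A = A, alpha = alpha, lfc_threshold = lfc_threshold,
                 correction = correction), class = "mas_params")
}

#' Magnitude-Altitude Score
#' @param log2fc Log2 fold change(s).
#' @param p_adj Adjusted p-value(s) in (0, 1].
#' @param params [mas_params()].
#' @return Non-negative score(s); 0 when `p_adj = 1` or `log2fc = 0`.
#' @export
mas_score <- function(log2fc, p_adj, params = mas_params()) {
  if (any(p_adj <= 0 | p_adj > 1))
    gq_stop("glmqlmas_error_precondition",
            "adjusted p-values must lie in (0, 1] (clamp upstream)")
  abs(log2fc)^params$M * abs(log10(p_adj))^params$A
}

p_column <- function(correction) {
  switch(correction, BH = "p_BH", bonferroni = "p_bonf", raw = "p_value")
}

#' Gate, classify and rank genes by MAS
#'
#' Keeps genes with adjusted p below `alpha` and `|log2FC|` strictly above
#' the threshold; direction is up for `log2FC > t`, down for
#' `log2FC < -t`. Sorted by MAS descending, ties broken by larger
#' `|log2FC|`, then lexicographic gene ID.
#'
#' @param de A `de_table` from [ql_f_test()]/[de_analysis()].
#' @param params [mas_params()].
#' @return Data frame `gene_id`, `log2FC`, `p_adj`, `MAS`, `direction`,
#'   `rank` (empty when nothing passes).
#' @export
rank_and_classify <- function(de, params = mas_params()) {
  pcol <- p_column(params$correction)
  p_adj <- de[[pcol]]
  t <- params$lfc_threshold
  keep <- p_adj < params$alpha & abs(de$log2FC) > t
  out <- data.frame(gene_id = de$gene_id[keep],
                    log2FC = de$log2FC[keep],
                    p_adj = p_adj[keep],
                    stringsAsFactors = FALSE)
  out$MAS <- mas_score(out$log2FC, pmax(out$p_adj, 1e-300), params)
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  ord <- order(-out$MAS, -abs(out$log2FC), out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Threshold-stability sweep of the MAS ranking
#'
#' For each |log2FC| threshold, counts significant up/down genes and
#' records the top `top_k` per direction by MAS. Counts are non-increasing
#' in the threshold, and the top-k set at threshold t equals the top-k of
#' the threshold-0 ranking restricted to genes passing t — the ranking is
#' threshold-independent.
#'
#' @param de A `de_table`.
#' @param thresholds Ascending thresholds (default `0:7`).
#' @param top_k Genes listed per direction (default 10).
#' @param params [mas_params()]; its `lfc_threshold` is overridden by each
#'   sweep value.
#' @return Data frame with one row per threshold x direction: `threshold`,
#'   `direction`, `n_significant`, `top_genes` (comma-separated, MAS
#'   order).
#' @export
threshold_sweep <- function(de, thresholds = 0:7, top_k = 10,
                            params = mas_params()) {
  if (is.unsorted(thresholds))
    gq_stop("glmqlmas_error_precondition", "thresholds must be ascending")
  rows <- lapply(thresholds, function(t) {
    pt <- params; pt$lfc_threshold <- t
    ranked <- rank_and_classify(de, pt)
    do.call(rbind, lapply(c("up", "down"), function(dir) {
      sel <- ranked[ranked$direction == dir, , drop = FALSE]
      data.frame(threshold = t, direction = dir, n_significant = nrow(sel),
                 top_genes = paste(utils::head(sel$gene_id, top_k),
                                   collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
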