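# Quasi-likelihood moderation and F-test. Raw quasi-dispersions are the
# per-gene residual deviances divided by residual df; their log-scale
# spread is moment-matched to the theoretical scaled-F distribution
# (trigamma inversion) to estimate a prior (d0, s2_0), and moderated
# dispersions are the df-weighted average of raw and prior. The group
# effect is tested with F = (deviance drop / df_test) / s2_post against
# F(df_test, d0 + d_g).

#' Empirical-Bayes moderation of quasi-likelihood dispersions
#'
#' @param fit Full-model `nb_glm_fit` (needs >= 10 genes for a stable
#'   prior).
#' @return List of class `ql_fit`: `s2_raw`, `df_residual`, `df_prior`
#'   (`Inf` when the log-dispersions are underdispersed relative to their
#'   theoretical spread), `s2_prior`, `s2_post`.
#' @export
ql_moderate <- function(fit) {
  d <- fit$df_residual
  if (d < 1)
    gq_stop("glmqlmas_error_precondition", "no residual degrees of freedom")
  s2 <- pmax(fit$deviance / d, 1e-8)   # floor guards log of exact-zero deviance
  G <- length(s2)
  if (G < 10L)
    gq_stop("glmqlmas_error_precondition",
            "at least 10 genes required to estimate the prior")
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s2_0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    gq_warn("log quasi-dispersions underdispersed; prior df set to Inf")
    d0 <- Inf
    # degenerate spread: the prior collapses to the central raw dispersion,
    # so an all-equal input is a fixed point of the moderation
    s2_0 <- exp(mean(log(s2)))
  }
  s2_post <- if (is.infinite(d0)) rep(s2_0, G) else
    (d0 * s2_0 + d * s2) / (d0 + d)
  structure(list(s2_raw = s2, df_residual = d, df_prior = d0,
                 s2_prior = s2_0, s2_post = s2_post),
            class = "ql_fit")
}

#' Quasi-likelihood F-test of the group effect
#'
#' @param full,reduced Nested `nb_glm_fit` objects (reduced = intercept
#'   only; one tested coefficient).
#' @param ql `ql_fit` from [ql_moderate()] on the full fit.
#' @param logcpm Optional log-CPM matrix for the `avg_logCPM` column.
#' @return Data frame (`de_table`): `gene_id`, `log2FC` (group coefficient
#'   / ln 2), `avg_logCPM`, `F`, `p_value`, `p_BH`, `p_bonf`. p-values are
#'   clamped at 1e-300 so downstream log10 is finite.
#' @export
ql_f_test <- function(full, reduced, ql, logcpm = NULL) {
  if (reduced$df_residual <= full$df_residual)
    gq_stop("glmqlmas_error_precondition", "reduced model must be nested in full")
  df_test <- reduced$df_residual - full$df_residual
  dd <- reduced$deviance - full$deviance
  if (any(dd < -1e-8))
    gq_stop("glmqlmas_error_numeric",
            "negative deviance difference: reduced model fits better than full")
  dd <- pmax(dd, 0)
  F_stat <- (dd / df_test) / ql$s2_post
  df2 <- ql$df_prior + full$df_residual
  p <- stats::pf(F_stat, df_test, df2, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-300), 1)
  gene_id <- rownames(full$fitted)
  if (is.null(gene_id)) gene_id <- sprintf("g%d", seq_along(p))
  out <- data.frame(
    gene_id = gene_id,
    log2FC = full$coefficients[, 2L] / log(2),
    avg_logCPM = if (is.null(logcpm)) NA_real_ else rowMeans(logcpm),
    F = F_stat,
    p_value = p,
    p_BH = adjust_pvalues(p, "BH"),
    p_bonf = adjust_pvalues(p, "bonferroni"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni family-wise adjustment
#' (via [stats::p.adjust()]), with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    gq_stop("glmqlmas_error_precondition", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Full differential-expression analysis of a two-group cohort
#'
#' Convenience wrapper running the pipeline's statistical core on a
#' filtered count matrix: TMM effective library sizes as offsets, common NB
#' dispersion by Cox-Reid profile likelihood, full and reduced GLM fits,
#' quasi-likelihood moderation, and the QL F-test with BH and Bonferroni
#' adjusted p-values.
#'
#' @param counts Count matrix (after cohort/gene filtering).
#' @param annotation Matching [sample_annotation()] (two groups).
#' @param factors Optional precomputed [tmm_normalize()] result.
#' @param dispersion Optional fixed NB dispersion; estimated when `NULL`.
#' @param dispersion_genes Gene cap passed to
#'   [estimate_common_dispersion()] (default 1000 for speed on large
#'   matrices).
#' @return List of class `de_fit`: `table` (the `de_table`), `fit_full`,
#'   `fit_reduced`, `ql`, `factors`, `dispersion`, `logcpm`.
#' @export
de_analysis <- function(counts, annotation, factors = NULL, dispersion = NULL,
                        dispersion_genes = 1000L) {
  keep <- match(colnames(counts), annotation$sample_id)
  if (anyNA(keep))
    gq_stop("glmqlmas_error_precondition",
            "count matrix samples missing from annotation")
  annotation <- annotation[keep, , drop = FALSE]
  if (is.null(factors)) factors <- tmm_normalize(counts)
  design <- build_design(annotation)
  offset <- log(factors$effective_library_size)
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(counts, design, offset,
                                             subset_genes = dispersion_genes)
  full <- fit_nb_glm(counts, design, offset, dispersion)
  reduced <- fit_nb_glm(counts, design[, 1L, drop = FALSE], offset, dispersion)
  ql <- ql_moderate(full)
  lc <- log_cpm(counts, factors)
  tab <- ql_f_test(full, reduced, ql, logcpm = lc)
  structure(list(table = tab, fit_full = full, fit_reduced = reduced, ql = ql,
                 factors = factors, dispersion = dispersion, logcpm = lc),
            class = "de_fit")
}
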