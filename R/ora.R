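# Over-representation analysis: hypergeometric upper-tail test of the
# overlap between a significant gene list and each gene set, within a
# stated universe, with BH q-values computed across the tested collection.

#' Hypergeometric over-representation analysis
#'
#' For each set with universe-restricted size K in `[min_size, max_size]`,
#' tests the overlap k of the significant list (size n) against the
#' universe (size N): `p = P(X >= k)` with X hypergeometric(N, K, n), the
#' observed overlap included. q-values are BH-adjusted p across tested
#' sets. Results are invariant to gene and set ordering.
#'
#' @param sig_genes Character vector of significant genes. Genes outside
#'   the universe are dropped with a warning.
#' @param universe Character vector: the background gene universe.
#' @param sets Named list of member-ID vectors (see [read_gmt()]).
#' @param min_size,max_size Universe-restricted set-size bounds for
#'   testing (defaults 5, 2000).
#' @return Data frame sorted by q, then p, then term name: `term`,
#'   `overlap_genes` (comma-separated), `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
ora <- function(sig_genes, universe, sets, min_size = 5L, max_size = 2000L) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L)
    gq_stop("glmqlmas_error_precondition", "empty gene universe")
  sig_genes <- unique(sig_genes)
  outside <- setdiff(sig_genes, universe)
  if (length(outside)) {
    gq_warn(paste(length(outside),
                  "significant genes outside the universe were dropped"))
    sig_genes <- intersect(sig_genes, universe)
  }
  n <- length(sig_genes)
  members <- lapply(sets, function(s) intersect(unique(s), universe))
  K <- lengths(members)
  test <- which(K >= min_size & K <= max_size)
  if (!length(test)) {
    out <- data.frame(term = character(0), overlap_genes = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  overlap <- lapply(members[test], intersect, x = sig_genes)
  k <- lengths(overlap)
  # upper tail including the observed overlap
  p <- stats::phyper(k - 1, K[test], N - K[test], n, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-300), 1)
  out <- data.frame(term = names(sets)[test],
                    overlap_genes = vapply(overlap, function(g)
                      paste(sort(g), collapse = ","), character(1)),
                    k = as.integer(k), K = as.integer(K[test]),
                    n = n, N = N, p = p,
                    q = adjust_pvalues(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top enriched terms
#' @param results Sorted data frame from [ora()].
#' @param n Number of terms to return (default 10).
#' @param by Ranking column, `"q"` or `"p"`.
#' @return The first `n` rows after re-sorting by `by`, then p, then term
#'   name (deterministic ties).
#' @export
top_terms <- function(results, n = 10L, by = c("q", "p")) {
  by <- match.arg(by)
  ord <- order(results[[by]], results$p, results$term)
  utils::head(results[ord, , drop = FALSE], n)
}
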