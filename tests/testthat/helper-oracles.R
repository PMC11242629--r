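# Independent straight-line oracles used across tests. These share no code
# with the package implementation paths they check.

# Benjamini-Hochberg step-up, written directly from the definition:
# sort p ascending, adjusted_(i) = min over j >= i of min(1, m p_(j) / j),
# mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * ps[i] / i)
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

bonferroni_oracle <- function(p) pmin(1, length(p) * p)

# TMM factor by direct evaluation of the defining formula.
tmm_oracle <- function(test, ref, lib_test, lib_ref,
                       trim_M = 0.30, trim_A = 0.05) {
  ok <- test > 0 & ref > 0
  yt <- test[ok]; yr <- ref[ok]
  M <- log2((yt / lib_test) / (yr / lib_ref))
  A <- 0.5 * log2((yt / lib_test) * (yr / lib_ref))
  w <- (lib_test - yt) / (lib_test * yt) + (lib_ref - yr) / (lib_ref * yr)
  n <- length(M)
  lo_m <- floor(n * trim_M) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_A) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(M) >= lo_m & rank(M) <= hi_m &
    rank(A) >= lo_a & rank(A) <= hi_a
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# Hypergeometric upper tail P(X >= k) by exhaustive combinatorial
# enumeration (feasible for N <= 30).
hyper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force MAS ranking: score every gene independently, filter, sort.
mas_oracle <- function(de, M = 1, A = 1, alpha = 0.05, t = 1, pcol = "p_BH") {
  rows <- list()
  for (i in seq_len(nrow(de))) {
    p <- de[[pcol]][i]; lfc <- de$log2FC[i]
    if (p < alpha && abs(lfc) > t) {
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = de$gene_id[i], log2FC = lfc, p_adj = p,
                   MAS = abs(lfc)^M * abs(log10(max(p, 1e-300)))^A,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(character(0))
  tab <- do.call(rbind, rows)
  tab$gene_id[order(-tab$MAS, -abs(tab$log2FC), tab$gene_id)]
}

# Small default cohort simulation used by many tests.
small_sim <- function(seed = 1, n_genes = 300, n_coding = 250,
                      group_sizes = c(30, 20), de_fraction = 0.1,
                      de_log2fc_magnitudes = c(2, 3), dispersion = 0.1, ...) {
  generate_cohort(sim_config(
    n_genes = n_genes, n_coding = n_coding, group_sizes = group_sizes,
    de_fraction = de_fraction, de_log2fc_magnitudes = de_log2fc_magnitudes,
    dispersion = dispersion, seed = seed, ...))
}

# Random DE-shaped table for ranking oracles.
random_de_table <- function(n, seed) {
  set.seed(seed)
  p <- runif(n)^3
  tab <- data.frame(gene_id = sprintf("g%03d", sample.int(9 * n, n)),
                    log2FC = rnorm(n, 0, 2),
                    p_value = p,
                    stringsAsFactors = FALSE)
  tab$p_BH <- stats::p.adjust(p, "BH")
  tab$p_bonf <- stats::p.adjust(p, "bonferroni")
  tab
}
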