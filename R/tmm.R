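# Trimmed mean of M-values (TMM) between-sample normalization, implemented
# from its defining formulas. For a test/reference library pair, per-gene
# log-ratios M and average log-abundances A are computed on library-scaled
# counts, both tails of M and of A are trimmed, and the normalization
# factor is 2 to the precision-weighted mean of the surviving M values.
# Factors are rescaled to geometric mean 1, and effective library sizes
# (library size x factor) feed the GLM offsets and log-CPM.

#' Choose the TMM reference sample
#'
#' The reference is the sample whose 75th percentile of library-size-scaled
#' counts is closest to the mean of those upper quartiles; ties go to the
#' lowest sample index.
#'
#' @param counts Count matrix with at least two samples.
#' @return Integer column index of the reference sample.
#' @export
choose_reference <- function(counts) {
  if (ncol(counts) < 2L)
    gq_stop("glmqlmas_error_precondition", "at least two samples required")
  lib <- colSums(counts)
  if (any(lib == 0))
    gq_stop("glmqlmas_error_integrity", "all-zero sample column")
  f75 <- apply(counts, 2L, function(y) stats::quantile(y, 0.75)) / lib
  unname(which.min(abs(f75 - mean(f75))))
}

#' TMM normalization factor for one library pair
#'
#' Restricted to genes with positive counts in both samples. Per gene,
#' \eqn{M = \log_2((y_t/N_t)/(y_r/N_r))} and
#' \eqn{A = \frac12 \log_2((y_t/N_t)(y_r/N_r))}; the top and bottom
#' `trim_M` fraction by M and `trim_A` fraction by A are discarded
#' (intersection of survivors) and the factor is
#' \eqn{2^{\sum w_g M_g / \sum w_g}} with inverse asymptotic-variance
#' weights \eqn{w_g = 1/[(N_t-y_t)/(N_t y_t) + (N_r-y_r)/(N_r y_r)]}.
#'
#' @param test,ref Count vectors of equal length.
#' @param lib_test,lib_ref Library sizes (default: vector sums).
#' @param trim_M,trim_A Two-sided trim fractions (defaults 0.30, 0.05).
#' @return Positive scalar factor; exactly 1 for a sample against itself,
#'   and 1 with a warning if no genes survive trimming.
#' @export
tmm_factor <- function(test, ref, lib_test = sum(test), lib_ref = sum(ref),
                       trim_M = 0.30, trim_A = 0.05) {
  stopifnot(length(test) == length(ref), lib_test > 0, lib_ref > 0)
  pos <- test > 0 & ref > 0
  yt <- test[pos]; yr <- ref[pos]
  if (length(yt) == 0L) {
    gq_warn("no genes with positive counts in both samples; TMM factor set to 1")
    return(1)
  }
  pt <- yt / lib_test; pr <- yr / lib_ref
  M <- log2(pt / pr)
  A <- 0.5 * log2(pt * pr)
  w <- 1 / ((lib_test - yt) / (lib_test * yt) + (lib_ref - yr) / (lib_ref * yr))

  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    gq_warn("no genes survive TMM trimming; factor set to 1")
    return(1)
  }
  wm <- sum(w[keep] * M[keep]) / sum(w[keep])
  if (!is.finite(wm)) {
    gq_warn("non-finite trimmed mean in TMM; factor set to 1")
    return(1)
  }
  if (abs(wm) < 1e-10) return(1)  # self-comparison and pure-depth exactness
  2^wm
}

#' TMM normalization factors for a count matrix
#'
#' Computes each sample's factor against the [choose_reference()] sample and
#' rescales all factors to geometric mean 1.
#'
#' @param counts Count matrix (>= 2 samples).
#' @param trim_M,trim_A Trim fractions passed to [tmm_factor()].
#' @return Data frame of class `norm_factors` with `sample_id`,
#'   `library_size`, `tmm_factor`, `effective_library_size`.
#' @export
tmm_normalize <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  ref <- choose_reference(counts)
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else
      tmm_factor(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A)
  }, numeric(1))
  f <- f / geo_mean(f)
  out <- data.frame(sample_id = colnames(counts),
                    library_size = lib,
                    tmm_factor = f,
                    effective_library_size = lib * f,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' Stabilized log2 counts per million
#'
#' With effective library sizes \eqn{L_i} and prior count \eqn{p}, each
#' sample's prior is depth-scaled, \eqn{p_i = p L_i / \bar L}, and
#' \deqn{logCPM_{gi} = \log_2\left(10^6 (y_{gi} + p_i) / (L_i + 2 p_i)\right).}
#' Strictly monotone in the count.
#'
#' @param counts Count matrix.
#' @param factors `norm_factors` from [tmm_normalize()] (must match samples).
#' @param prior Positive prior count (default 1).
#' @return Real matrix of the same dimensions as `counts`.
#' @export
log_cpm <- function(counts, factors = tmm_normalize(counts), prior = 1) {
  stopifnot(identical(factors$sample_id, colnames(counts)), prior > 0)
  eff <- factors$effective_library_size
  pc <- prior * eff / mean(eff)
  t(log2(t(counts) + pc) - log2(eff + 2 * pc)) + log2(1e6)
}
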