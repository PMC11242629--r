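# Synthetic RNA-seq cohort generator. Emulates the statistical structure the
# downstream analysis assumes: discrete negative-binomial counts with
# gene-wise overdispersion, variable library sizes, a two-group nodal-status
# design (ALNM+/ALNM-), optional one-group composition bias, and a planted
# fraction of truly differential protein-coding genes with known log2 fold
# changes. Ground truth is returned for recovery tests.

#' Simulation configuration
#'
#' Defaults mirror the study cohort the pipeline targets: a 60,660-gene
#' annotated universe with 19,938 protein-coding genes, and 65 ALNM-negative
#' versus 42 ALNM-positive untreated samples. Counts for gene g in sample i
#' are negative binomial with mean
#' \eqn{\lambda_g s_i 2^{x_i \beta_g}} (group indicator \eqn{x_i}, planted
#' log2 fold change \eqn{\beta_g}) and variance \eqn{\mu + \phi \mu^2};
#' `dispersion = 0` degenerates to Poisson.
#'
#' @param n_genes Total genes in the annotated universe.
#' @param n_coding Number of protein-coding genes (`<= n_genes`).
#' @param group_sizes Integer pair: ALNM-negative, ALNM-positive sample counts.
#' @param baseline_log_mean_range Natural-log interval for baseline mean
#'   counts; baselines are drawn log-uniformly over it to span low through
#'   high expression.
#' @param dispersion NB dispersion \eqn{\phi \ge 0}: a scalar or a per-gene
#'   vector.
#' @param libsize_factors Per-sample positive multipliers of sequencing
#'   depth; `NULL` draws log-normal factors (sdlog 0.3).
#' @param de_fraction Fraction of genes that are truly differential
#'   (planted among protein-coding genes).
#' @param de_log2fc_magnitudes Positive magnitudes sampled (with random
#'   sign) for planted log2 fold changes.
#' @param composition_bias_fraction Fraction of genes expressed at 20x
#'   baseline in the ALNM-positive group only — a normalization stressor
#'   whose truth is flagged separately from planted DE.
#' @param missing_alnm_count,treated_count Extra samples with missing nodal
#'   status / prior treatment, for cohort-filter fixtures.
#' @param seed Master seed; component sub-streams use fixed offsets.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60660L, n_coding = 19938L,
                       group_sizes = c(65L, 42L),
                       baseline_log_mean_range = c(1, 8),
                       dispersion = 0.1,
                       libsize_factors = NULL,
                       de_fraction = 0.1,
                       de_log2fc_magnitudes = c(1, 2, 3),
                       composition_bias_fraction = 0,
                       missing_alnm_count = 0L, treated_count = 0L,
                       seed = 1L) {
  if (!all(is.finite(c(n_genes, n_coding, group_sizes, baseline_log_mean_range,
                       dispersion, de_fraction, composition_bias_fraction,
                       missing_alnm_count, treated_count, seed))))
    gq_stop("glmqlmas_error_config", "non-finite simulation configuration value")
  if (any(c(n_genes, group_sizes) <= 0) || n_coding > n_genes || n_coding <= 0)
    gq_stop("glmqlmas_error_config", "invalid gene or group sizes")
  if (any(dispersion < 0) || de_fraction < 0 || de_fraction > 1 ||
      composition_bias_fraction < 0 || composition_bias_fraction >= 1)
    gq_stop("glmqlmas_error_config", "negative dispersion or out-of-range fraction")
  if (!is.null(libsize_factors) && any(libsize_factors <= 0))
    gq_stop("glmqlmas_error_config", "library size factors must be positive")
  structure(list(n_genes = as.integer(n_genes), n_coding = as.integer(n_coding),
                 group_sizes = as.integer(group_sizes),
                 baseline_log_mean_range = baseline_log_mean_range,
                 dispersion = dispersion, libsize_factors = libsize_factors,
                 de_fraction = de_fraction,
                 de_log2fc_magnitudes = de_log2fc_magnitudes,
                 composition_bias_fraction = composition_bias_fraction,
                 missing_alnm_count = as.integer(missing_alnm_count),
                 treated_count = as.integer(treated_count),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic two-group RNA-seq cohort
#'
#' Draws counts, sample annotation (ALNM labels, treatment flags), gene
#' annotation (biotypes) and a ground-truth table. Deterministic given the
#' config seed: gene-level parameters, library sizes and counts are drawn
#' from fixed seed sub-streams.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (count matrix), `samples`
#'   ([sample_annotation()]), `genes` (data frame `gene_id`, `biotype`),
#'   `truth` (data frame `gene_id`, `is_de`, `true_log2fc`, `biotype`,
#'   `comp_bias`) and `sample_scale` (the true per-sample depth factors,
#'   the target TMM effective scales estimate).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genes
  n_neg <- config$group_sizes[1L]; n_pos <- config$group_sizes[2L]
  n_extra <- config$missing_alnm_count + config$treated_count
  n <- n_neg + n_pos + n_extra

  gene_ids <- sprintf("G%05d", seq_len(G))
  sample_ids <- sprintf("S%04d", seq_len(n))

  # sub-stream 0: gene-level parameters (baselines, biotypes, planted truth)
  set.seed(substream_seed(config$seed, 0L))
  lo <- config$baseline_log_mean_range[1L]; hi <- config$baseline_log_mean_range[2L]
  lambda <- exp(stats::runif(G, lo, hi))
  coding <- sample.int(G, config$n_coding)
  biotype <- rep("other", G)
  noncoding <- setdiff(seq_len(G), coding)
  if (length(noncoding))
    biotype[noncoding] <- sample(c("lncRNA", "miRNA", "pseudogene", "other"),
                                 length(noncoding), replace = TRUE)
  biotype[coding] <- "protein_coding"

  n_de <- round(config$de_fraction * G)
  if (n_de > config$n_coding)
    gq_stop("glmqlmas_error_config", "more DE genes requested than coding genes")
  de_idx <- if (n_de > 0) resample(coding, n_de) else integer(0)
  beta2 <- numeric(G)  # log2 scale
  if (n_de > 0)
    beta2[de_idx] <- resample(config$de_log2fc_magnitudes, n_de, replace = TRUE) *
      sample(c(-1, 1), n_de, replace = TRUE)
  n_comp <- round(config$composition_bias_fraction * G)
  comp_idx <- if (n_comp > 0) resample(setdiff(seq_len(G), de_idx), n_comp) else integer(0)

  # sub-stream 1: per-sample depth factors
  set.seed(substream_seed(config$seed, 1L))
  s <- config$libsize_factors
  if (is.null(s)) s <- stats::rlnorm(n, meanlog = 0, sdlog = 0.3)
  if (length(s) != n)
    gq_stop("glmqlmas_error_config", "libsize_factors length must equal total samples")

  # group indicator for count generation; extra (filtered) samples are drawn
  # as baseline ALNM- so they carry no planted effect
  x <- c(rep(0, n_neg), rep(1, n_pos), rep(0, n_extra))

  mu <- outer(lambda, s) * 2^(beta2 %o% x)
  if (n_comp > 0)
    mu[comp_idx, x == 1] <- mu[comp_idx, x == 1] * 20

  # sub-stream 2: counts
  set.seed(substream_seed(config$seed, 2L))
  phi <- rep_len(config$dispersion, G)
  y <- matrix(0, G, n)
  pois <- phi == 0
  if (any(pois))
    y[pois, ] <- stats::rpois(sum(pois) * n, lambda = mu[pois, , drop = FALSE])
  if (any(!pois))
    y[!pois, ] <- stats::rnbinom(sum(!pois) * n,
                                 mu = mu[!pois, , drop = FALSE],
                                 size = 1 / phi[!pois])
  counts <- count_matrix(y, gene_ids = gene_ids, sample_ids = sample_ids)

  status <- c(rep("negative", n_neg), rep("positive", n_pos))
  chemo <- radio <- logical(n)
  if (n_extra > 0) {
    extra_status <- c(rep("missing", config$missing_alnm_count),
                      rep(c("negative", "positive"),
                          length.out = config$treated_count))
    status <- c(status, extra_status)
    treated <- n_neg + n_pos + config$missing_alnm_count + seq_len(config$treated_count)
    chemo[treated] <- rep(c(TRUE, FALSE), length.out = config$treated_count)
    radio[treated] <- !chemo[treated]
  }
  samples <- sample_annotation(sample_ids, status,
                               prior_chemo = chemo, prior_radio = radio)

  genes <- data.frame(gene_id = gene_ids, biotype = biotype,
                      stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_ids,
                      is_de = beta2 != 0,
                      true_log2fc = beta2,
                      biotype = biotype,
                      comp_bias = seq_len(G) %in% comp_idx,
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, genes = genes, truth = truth,
       sample_scale = s)
}

#' Generate random gene-set collections, optionally with a planted set
#'
#' Draws `n_sets` sets without replacement from `gene_ids`. When a truth
#' table is supplied, one additional set named `"PLANTED_DE"` is built to
#' contain `planted_fraction` true-DE genes (fixture for enrichment
#' recovery tests).
#'
#' @param gene_ids Non-empty character vector: the gene universe.
#' @param n_sets Number of random sets.
#' @param set_size_range Integer interval of set sizes.
#' @param planted_set_from Optional truth table from [generate_cohort()].
#' @param planted_fraction Fraction of the planted set drawn from true-DE
#'   genes (default 0.8).
#' @param planted_size Size of the planted set (default 20).
#' @param seed Integer seed.
#' @return Named list of member-ID vectors (GMT-compatible).
#' @export
generate_gene_sets <- function(gene_ids, n_sets, set_size_range = c(10L, 100L),
                               planted_set_from = NULL, planted_fraction = 0.8,
                               planted_size = 20L, seed = 1L) {
  if (length(gene_ids) == 0L)
    gq_stop("glmqlmas_error_config", "empty gene universe")
  if (max(set_size_range) > length(gene_ids))
    gq_stop("glmqlmas_error_config", "set size exceeds gene universe")
  set.seed(substream_seed(seed, 3L))
  sets <- list()
  if (n_sets > 0) {
    sizes <- resample(seq(set_size_range[1L], set_size_range[2L]), n_sets,
                    replace = TRUE)
    sets <- lapply(seq_len(n_sets), function(i) resample(gene_ids, sizes[i]))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
  }
  if (!is.null(planted_set_from)) {
    de_genes <- intersect(planted_set_from$gene_id[planted_set_from$is_de], gene_ids)
    n_from_de <- round(planted_fraction * planted_size)
    if (length(de_genes) < n_from_de)
      gq_stop("glmqlmas_error_config", "not enough true-DE genes for planted set")
    other <- setdiff(gene_ids, de_genes)
    planted <- c(resample(de_genes, n_from_de),
                 resample(other, planted_size - n_from_de))
    sets <- c(sets, list(PLANTED_DE = planted))
  }
  if (length(sets) == 0L) names(sets) <- character(0)
  attr(sets, "description") <- stats::setNames(rep("synthetic", length(sets)),
                                               names(sets))
  sets
}
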