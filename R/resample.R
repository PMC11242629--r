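# Balanced-resampling directional-consistency selection ("Case 2"). The
# majority (ALNM-) group is subsampled to the minority size, the full
# analysis (TMM -> NB QL GLM -> BH) is re-run on each balanced cohort, and
# per gene the number of iterations in which it is BH-significant up or
# down at each |log2FC| threshold is counted. Biomarkers must recur in at
# least half the iterations in one direction with no opposite-direction
# occurrences; genes recurring in every iteration form the strongest tier.

#' Resampling configuration
#' @param R Number of balanced iterations (default 500).
#' @param subsample_size Majority-group samples drawn per iteration;
#'   `NULL` uses the minority group size.
#' @param min_count Minimum same-direction significant occurrences to
#'   qualify (default `ceiling(R / 2)`).
#' @param lfc_thresholds Absolute log2FC thresholds counted (default 1:6).
#' @param base_seed Seed for iteration 0; iteration i uses `base_seed + i`.
#' @param allow_opposite_count Maximum tolerated opposite-direction
#'   occurrences (default 0: unequivocal direction).
#' @return List of class `resampling_config`.
#' @export
resampling_config <- function(R = 500L, subsample_size = NULL,
                              min_count = ceiling(R / 2),
                              lfc_thresholds = 1:6, base_seed = 1L,
                              allow_opposite_count = 0L) {
  stopifnot(R >= 1, min_count <= R, all(lfc_thresholds > 0),
            allow_opposite_count >= 0)
  structure(list(R = as.integer(R), subsample_size = subsample_size,
                 min_count = as.integer(min_count),
                 lfc_thresholds = lfc_thresholds,
                 base_seed = as.integer(base_seed),
                 allow_opposite_count = as.integer(allow_opposite_count)),
            class = "resampling_config")
}

#' Run the balanced resampling analysis
#'
#' Iteration i (seed `base_seed + i`) samples `subsample_size`
#' majority-group samples without replacement, joins them with all
#' minority-group samples, and re-runs the full per-cohort analysis:
#' all-zero genes of the subsample are dropped (they count as not
#' significant that iteration), TMM factors are recomputed, the common
#' dispersion re-estimated, and BH correction applied within the
#' iteration. Deterministic given seeds and independent of iteration
#' execution order.
#'
#' @param counts Filtered count matrix.
#' @param annotation Matching two-group [sample_annotation()].
#' @param config [resampling_config()].
#' @param alpha BH significance level per iteration (default 0.05).
#' @param dispersion_genes Gene cap for per-iteration dispersion
#'   estimation (default 500).
#' @return List of class `resampling_summary`: `up`, `down` (gene x
#'   threshold integer matrices of occurrence counts), `R`, `config`.
#' @export
run_resampling <- function(counts, annotation, config = resampling_config(),
                           alpha = 0.05, dispersion_genes = 500L) {
  status <- as.character(annotation$alnm_status)
  tab <- table(status[status != "missing"])
  if (length(tab) != 2L)
    gq_stop("glmqlmas_error_precondition", "two groups required")
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  m <- config$subsample_size
  if (is.null(m)) m <- min(tab)
  if (m > max(tab))
    gq_stop("glmqlmas_error_precondition",
            "subsample size exceeds majority group size")
  maj_ids <- annotation$sample_id[status == majority]
  min_ids <- annotation$sample_id[status == minority]

  th <- config$lfc_thresholds
  up <- down <- matrix(0L, nrow(counts), length(th),
                       dimnames = list(rownames(counts), paste0("t", th)))
  for (i in seq_len(config$R)) {
    set.seed(substream_seed(config$base_seed, 0L) + i)
    picked <- resample(maj_ids, m)
    ids <- c(picked, min_ids)
    sub_counts <- counts[, ids, drop = FALSE]
    sub_annot <- annotation[match(ids, annotation$sample_id), , drop = FALSE]
    dz <- drop_unexpressed(sub_counts)
    fit <- de_analysis(dz$counts, sub_annot, dispersion_genes = dispersion_genes)
    de <- fit$table
    sig <- de$p_BH < alpha
    gi <- match(de$gene_id, rownames(counts))
    for (j in seq_along(th)) {
      up_hit <- gi[sig & de$log2FC > th[j]]
      down_hit <- gi[sig & de$log2FC < -th[j]]
      up[up_hit, j] <- up[up_hit, j] + 1L
      down[down_hit, j] <- down[down_hit, j] + 1L
    }
  }
  structure(list(up = up, down = down, R = config$R, config = config),
            class = "resampling_summary")
}

#' Qualify biomarkers from a resampling summary
#'
#' A gene qualifies UP at a threshold iff its up-count is at least
#' `min_count` and its down-count does not exceed `allow_opposite_count`
#' (default 0); DOWN symmetrically. Genes qualifying with count = R form
#' the `"strongest"` (100%-consistency) tier. No gene appears in both
#' directions.
#'
#' @param summary `resampling_summary` from [run_resampling()].
#' @param threshold Which |log2FC| threshold column to use (default: the
#'   smallest).
#' @param config Defaults to the summary's own config.
#' @return Data frame `gene_id`, `up_count`, `down_count`, `qualified`,
#'   `direction` (`"up"`, `"down"`, `"none"`), `tier` (`"strongest"`,
#'   `"qualified"`, `"none"`), sorted by qualifying count descending.
#' @export
qualify <- function(summary, threshold = NULL, config = summary$config) {
  th <- config$lfc_thresholds
  j <- if (is.null(threshold)) 1L else match(threshold, th)
  if (is.na(j))
    gq_stop("glmqlmas_error_precondition", "threshold not present in summary")
  upc <- summary$up[, j]; downc <- summary$down[, j]
  R <- summary$R; mc <- config$min_count; opp <- config$allow_opposite_count
  up_ok <- upc >= mc & downc <= opp
  down_ok <- downc >= mc & upc <= opp
  direction <- ifelse(up_ok, "up", ifelse(down_ok, "down", "none"))
  qcount <- ifelse(up_ok, upc, ifelse(down_ok, downc, 0L))
  tier <- ifelse(direction == "none", "none",
                 ifelse(qcount == R, "strongest", "qualified"))
  out <- data.frame(gene_id = rownames(summary$up),
                    up_count = as.integer(upc), down_count = as.integer(downc),
                    qualified = direction != "none",
                    direction = direction, tier = tier,
                    stringsAsFactors = FALSE)
  out <- out[order(-qcount, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect full-cohort and resampling-qualified gene lists
#'
#' Per direction, the genes ranked in the full-cohort ("Case 1") MAS list
#' that also qualify in the resampling analysis ("Case 2"), preserving
#' Case-1 MAS order.
#'
#' @param case1 Ranked table from [rank_and_classify()].
#' @param case2 Biomarker table from [qualify()].
#' @return List with `up` and `down` character vectors.
#' @export
intersect_cases <- function(case1, case2) {
  common <- function(dir) {
    c1 <- case1$gene_id[case1$direction == dir]
    c2 <- case2$gene_id[case2$qualified & case2$direction == dir]
    c1[c1 %in% c2]
  }
  list(up = common("up"), down = common("down"))
}
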