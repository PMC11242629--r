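resample_sim <- function(seed = 31, n_genes = 200) {
  generate_cohort(sim_config(
    n_genes = n_genes, n_coding = n_genes, group_sizes = c(20, 12),
    de_fraction = 2 / n_genes, de_log2fc_magnitudes = 4, dispersion = 0.05,
    baseline_log_mean_range = c(4, 7), seed = seed))
}

test_that("a strongly planted gene is recovered in every iteration", {
  sim <- resample_sim()
  cfg <- resampling_config(R = 2, lfc_thresholds = 1:3, base_seed = 5)
  s <- suppressWarnings(run_resampling(sim$counts, sim$samples, cfg))
  planted <- sim$truth$gene_id[sim$truth$is_de]
  for (g in planted) {
    hits <- s$up[g, 1] + s$down[g, 1]
    expect_equal(unname(hits), 2L)
    # direction never flips
    expect_equal(unname(min(s$up[g, 1], s$down[g, 1])), 0L)
  }
})

test_that("resampling is deterministic given the base seed", {
  sim <- resample_sim(seed = 32)
  cfg <- resampling_config(R = 3, lfc_thresholds = 1:2, base_seed = 9)
  a <- suppressWarnings(run_resampling(sim$counts, sim$samples, cfg))
  b <- suppressWarnings(run_resampling(sim$counts, sim$samples, cfg))
  expect_identical(a$up, b$up)
  expect_identical(a$down, b$down)
})

test_that("counts are non-increasing in the |log2FC| threshold", {
  sim <- resample_sim(seed = 33)
  cfg <- resampling_config(R = 3, lfc_thresholds = 1:4, base_seed = 2)
  s <- suppressWarnings(run_resampling(sim$counts, sim$samples, cfg))
  expect_true(all(t(apply(s$up, 1, diff)) <= 0))
  expect_true(all(t(apply(s$down, 1, diff)) <= 0))
  expect_true(all(s$up + s$down <= s$R))
})

test_that("a single iteration equals the equivalent one-shot analysis", {
  sim <- resample_sim(seed = 34)
  cfg <- resampling_config(R = 1, lfc_thresholds = 1, base_seed = 7)
  s <- suppressWarnings(run_resampling(sim$counts, sim$samples, cfg))

  # reproduce iteration 1 by hand with the documented seed rule
  ann <- sim$samples
  maj <- ann$sample_id[ann$alnm_status == "negative"]
  set.seed(glmqlmas:::substream_seed(7L, 0L) + 1L)
  picked <- glmqlmas:::resample(maj, 12)
  ids <- c(picked, ann$sample_id[ann$alnm_status == "positive"])
  sub <- drop_unexpressed(sim$counts[, ids])$counts
  de <- suppressWarnings(
    de_analysis(sub, ann[match(ids, ann$sample_id), ],
                dispersion_genes = 500L))$table
  up_ids <- de$gene_id[de$p_BH < 0.05 & de$log2FC > 1]
  expect_identical(sort(rownames(s$up)[s$up[, 1] == 1]), sort(up_ids))
})

test_that("qualification enforces the half-count rule and unequivocal direction", {
  up <- matrix(c(500L, 251L, 249L, 0L), 4, 1,
               dimnames = list(c("a", "b", "c", "d"), "t1"))
  down <- matrix(c(0L, 1L, 0L, 260L), 4, 1,
                 dimnames = list(c("a", "b", "c", "d"), "t1"))
  s <- structure(list(up = up, down = down, R = 500L,
                      config = resampling_config(R = 500, lfc_thresholds = 1)),
                 class = "resampling_summary")
  q <- qualify(s)
  expect_identical(q$direction[q$gene_id == "a"], "up")
  expect_identical(q$tier[q$gene_id == "a"], "strongest")  # 500 of 500
  expect_false(q$qualified[q$gene_id == "b"])              # mixed trend
  expect_false(q$qualified[q$gene_id == "c"])              # below half
  expect_identical(q$direction[q$gene_id == "d"], "down")
  expect_identical(q$tier[q$gene_id == "d"], "qualified")
  # laxer reading via allow_opposite_count
  s$config <- resampling_config(R = 500, lfc_thresholds = 1,
                                allow_opposite_count = 5)
  q2 <- qualify(s)
  expect_true(q2$qualified[q2$gene_id == "b"])
})

test_that("case intersection preserves Case-1 order and matches brute force", {
  case1 <- data.frame(gene_id = c("g5", "g2", "g9", "g1", "g7"),
                      direction = c("up", "up", "down", "up", "down"),
                      stringsAsFactors = FALSE)
  case2 <- data.frame(gene_id = c("g1", "g2", "g7", "g3"),
                      qualified = c(TRUE, TRUE, TRUE, FALSE),
                      direction = c("up", "up", "down", "up"),
                      stringsAsFactors = FALSE)
  out <- intersect_cases(case1, case2)
  expect_identical(out$up, c("g2", "g1"))
  expect_identical(out$down, "g7")

  disjoint <- intersect_cases(case1,
                              data.frame(gene_id = "zz", qualified = TRUE,
                                         direction = "up"))
  expect_length(disjoint$up, 0L)

  set.seed(35)
  for (i in 1:10) {
    c1 <- data.frame(gene_id = sample(sprintf("g%02d", 1:30), 15),
                     direction = sample(c("up", "down"), 15, replace = TRUE),
                     stringsAsFactors = FALSE)
    c2 <- data.frame(gene_id = sample(sprintf("g%02d", 1:30), 15),
                     qualified = sample(c(TRUE, FALSE), 15, replace = TRUE),
                     direction = sample(c("up", "down"), 15, replace = TRUE),
                     stringsAsFactors = FALSE)
    out <- intersect_cases(c1, c2)
    for (dir in c("up", "down")) {
      brute <- c1$gene_id[c1$direction == dir &
                            vapply(c1$gene_id, function(g)
                              any(c2$gene_id == g & c2$qualified &
                                    c2$direction == dir), logical(1))]
      expect_identical(out[[dir]], brute)
    }
  }
})
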