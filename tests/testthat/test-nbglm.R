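two_group_annotation <- function(n_neg, n_pos) {
  sample_annotation(sprintf("s%03d", seq_len(n_neg + n_pos)),
                    c(rep("negative", n_neg), rep("positive", n_pos)))
}

test_that("design matrix encodes ALNM- as reference and is equivariant", {
  ann <- two_group_annotation(2, 2)
  X <- build_design(ann)
  expect_equal(unname(X), cbind(rep(1, 4), c(0, 0, 1, 1)))
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(build_design(ann[perm, ])), unname(X[perm, ]))
  one <- sample_annotation(c("a", "b"), c("negative", "negative"))
  expect_error(build_design(one), class = "glmqlmas_error_precondition")
})

test_that("group coefficient equals the log group-mean ratio under equal offsets", {
  set.seed(11)
  ann <- two_group_annotation(10, 8)
  X <- build_design(ann)
  y <- rnbinom(18, mu = rep(c(40, 90), c(10, 8)), size = 10)
  fit <- fit_nb_glm(y, X, offset = 0, phi = 0.1)
  expect_equal(unname(fit$coefficients[1, 2]),
               log(mean(y[11:18]) / mean(y[1:10])), tolerance = 1e-8)
  expect_equal(unname(exp(fit$coefficients[1, 1])), mean(y[1:10]),
               tolerance = 1e-6)
})

test_that("score equations hold and the Poisson limit matches stats::glm", {
  set.seed(12)
  X <- cbind(1, rep(c(0, 1), each = 12))
  off <- rnorm(24, 0, 0.2)
  y <- matrix(rnbinom(50 * 24, mu = exp(3 + 0.5 * X[, 2] + rep(off, each = 50)),
                      size = 10), 50, 24)
  fit <- fit_nb_glm(y, X, off, phi = 1e-12)
  score <- abs((y - fit$fitted) %*% X)   # phi ~ 0: unit score weights
  expect_lt(max(score), 1e-5)
  for (g in c(1, 17, 50)) {
    gfit <- glm(y[g, ] ~ X[, 2] + offset(off), family = poisson())
    expect_equal(unname(fit$coefficients[g, ]), unname(coef(gfit)),
                 tolerance = 1e-6)
  }
})

test_that("identical group distributions give zero effect and zero deviance drop", {
  X <- cbind(1, rep(c(0, 1), each = 6))
  y <- rep(c(5, 9, 13), 4)
  full <- fit_nb_glm(y, X, phi = 0.2)
  reduced <- fit_nb_glm(y, X[, 1, drop = FALSE], phi = 0.2)
  expect_equal(full$coefficients[1, 2], 0, tolerance = 1e-10)
  expect_equal(full$deviance, reduced$deviance, tolerance = 1e-10)
})

test_that("dispersion estimation recovers truth and matches a grid search", {
  set.seed(13)
  X <- cbind(1, rep(c(0, 1), each = 20))
  # Poisson data: estimate collapses to the lower boundary region
  y0 <- matrix(rpois(2000 * 40, lambda = exp(runif(2000, 2, 6))), 2000, 40)
  expect_lte(estimate_common_dispersion(y0, X), 0.01)
  # NB truth 0.1
  y1 <- matrix(rnbinom(2000 * 40, mu = exp(runif(2000, 2, 6)), size = 10),
               2000, 40)
  est <- estimate_common_dispersion(y1, X)
  expect_gte(est, 0.08); expect_lte(est, 0.12)

  # tiny fixture: optimizer agrees with an exhaustive grid on an
  # independently-coded Cox-Reid adjusted profile likelihood
  set.seed(14)
  Xs <- cbind(1, rep(c(0, 1), each = 6))
  ys <- matrix(rnbinom(30 * 12, mu = 60, size = 5), 30, 12)
  apl <- function(phi) {
    sum(vapply(seq_len(nrow(ys)), function(g) {
      fit <- suppressWarnings(fit_nb_glm(ys[g, ], Xs, 0, phi))
      mu <- fit$fitted[1, ]
      ll <- sum(dnbinom(ys[g, ], mu = mu, size = 1 / phi, log = TRUE))
      W <- diag(mu / (1 + phi * mu))
      ll - 0.5 * determinant(t(Xs) %*% W %*% Xs)$modulus
    }, numeric(1)))
  }
  grid <- exp(seq(log(1e-3), log(2), length.out = 200))
  grid_best <- grid[which.max(vapply(grid, apl, numeric(1)))]
  est_s <- estimate_common_dispersion(ys, Xs)
  expect_lt(abs(apl(est_s) - apl(grid_best)), 1e-2)
  expect_equal(log(est_s), log(grid_best), tolerance = 0.05)
})

test_that("QL moderation: fixed points, limits, and prior-df recovery", {
  mk_fit <- function(s2, d) {
    structure(list(deviance = s2 * d, df_residual = d,
                   fitted = matrix(1, length(s2), d + 2)),
              class = "nb_glm_fit")
  }
  # all raw dispersions equal -> moderated equal that value
  same <- suppressWarnings(ql_moderate(mk_fit(rep(1.7, 60), 20)))
  expect_equal(same$s2_post, rep(1.7, 60), tolerance = 1e-6)

  # scaled-F sample with known prior df 10
  set.seed(15)
  s2 <- 1.3 * rf(5000, 40, 10)
  ql <- ql_moderate(mk_fit(s2, 40))
  expect_gte(ql$df_prior, 5); expect_lte(ql$df_prior, 20)
  # moderated values lie between raw and prior
  lo <- pmin(ql$s2_raw, ql$s2_prior); hi <- pmax(ql$s2_raw, ql$s2_prior)
  expect_true(all(ql$s2_post >= lo - 1e-12 & ql$s2_post <= hi + 1e-12))

  # underdispersed log-s2 -> infinite prior df, all moderated to the prior
  expect_warning(
    tight <- ql_moderate(mk_fit(exp(rnorm(200, 0, 0.001)), 40)),
    "underdispersed")
  expect_true(is.infinite(tight$df_prior))
  expect_equal(unique(round(tight$s2_post, 10)),
               round(tight$s2_prior, 10))
})

test_that("QL F-test scales linearly and degenerates correctly", {
  set.seed(16)
  ann <- two_group_annotation(8, 8)
  X <- build_design(ann)
  y <- matrix(rnbinom(40 * 16, mu = 50, size = 8), 40, 16,
              dimnames = list(sprintf("g%02d", 1:40), ann$sample_id))
  full <- fit_nb_glm(y, X, phi = 0.1)
  red <- fit_nb_glm(y, X[, 1, drop = FALSE], phi = 0.1)
  ql <- ql_moderate(full)
  tab <- ql_f_test(full, red, ql)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$p_BH >= tab$p_value - 1e-15))
  expect_true(all(tab$p_bonf >= tab$p_value - 1e-15))

  # doubling the deviance drop doubles F
  red2 <- red
  red2$deviance <- full$deviance + 2 * (red$deviance - full$deviance)
  tab2 <- ql_f_test(full, red2, ql)
  expect_equal(tab2$F, 2 * tab$F, tolerance = 1e-12)

  # zero deviance difference -> F 0, p 1
  red0 <- red; red0$deviance <- full$deviance
  tab0 <- ql_f_test(full, red0, ql)
  expect_equal(tab0$F, rep(0, 40))
  expect_equal(tab0$p_value, rep(1, 40))

  # appreciable negative differences are a numerical error
  redn <- red; redn$deviance <- full$deviance - 1
  expect_error(ql_f_test(full, redn, ql), class = "glmqlmas_error_numeric")
})

test_that("BH and Bonferroni adjustments satisfy their definitions", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.37, "BH"), 0.37)
  expect_equal(adjust_pvalues(rep(0.2, 7), "BH"), rep(0.2, 7))
  expect_equal(adjust_pvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  expect_error(adjust_pvalues(c(0.1, 1.2)), class = "glmqlmas_error_precondition")
  # monotonicity: adjustment preserves p-value ordering
  set.seed(17)
  p <- runif(100)
  adj <- adjust_pvalues(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("swapping group labels negates log2FC and fixes F and p", {
  sim <- small_sim(seed = 18, n_genes = 120, n_coding = 120,
                   group_sizes = c(12, 10))
  de1 <- suppressWarnings(de_analysis(sim$counts, sim$samples))
  flipped <- sim$samples
  flipped$alnm_status <- factor(
    c(negative = "positive", positive = "negative")[
      as.character(sim$samples$alnm_status)],
    levels = levels(sim$samples$alnm_status))
  de2 <- suppressWarnings(de_analysis(sim$counts, flipped,
                                      dispersion = de1$dispersion))
  expect_equal(de2$table$log2FC, -de1$table$log2FC, tolerance = 1e-8)
  expect_equal(de2$table$F, de1$table$F, tolerance = 1e-8)
  expect_equal(de2$table$p_value, de1$table$p_value, tolerance = 1e-8)
})
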