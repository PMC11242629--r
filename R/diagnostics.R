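# Separability diagnostics: PCA of gene-standardized log-CPM, resubstitution
# logistic-regression metrics over the leading components, and the Fisher
# LDA1 one-dimensional projection of the top-ranked genes. These analyses
# illustrate class separability before versus after gene selection; they
# are deliberately not cross-validated prediction models.

#' Principal components of a log-CPM matrix
#'
#' Genes (rows) are centered and unit-scaled; samples are projected onto
#' the leading `k` right singular vectors. Zero-variance genes are dropped
#' with a warning. Sign convention: within each component the loading of
#' largest magnitude is positive.
#'
#' @param logcpm Genes x samples real matrix.
#' @param k Number of components, `<= min(samples - 1, genes)`.
#' @return Samples x k score matrix with attributes `sdev` (component
#'   standard deviations) and `provenance = "PCA"`.
#' @export
pca_embed <- function(logcpm, k) {
  X <- t(logcpm)                           # samples x genes
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    gq_warn(paste(sum(v == 0), "zero-variance genes dropped before PCA"))
    X <- X[, v > 0, drop = FALSE]
  }
  if (k > min(nrow(X) - 1L, ncol(X)))
    gq_stop("glmqlmas_error_precondition", "k exceeds available components")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  attr(scores, "sdev") <- pc$sdev[seq_len(k)]
  attr(scores, "provenance") <- "PCA"
  scores
}

#' Resubstitution logistic-regression separability metrics
#'
#' Fits an unregularized maximum-likelihood logistic regression of
#' ALNM-positive status on the embedding coordinates (Newton/IRLS, epsilon
#' 1e-10, up to 100 iterations), predicts on the same samples at
#' probability 0.5, and reports the confusion matrix with ALNM+ as the
#' positive class. Perfect separation is flagged (`separation = TRUE`) and
#' metrics are still reported from the capped fit. AUC uses the rank-sum
#' (Mann-Whitney) formulation on fitted scores, midranks for ties.
#'
#' @param embedding Samples x d coordinate matrix.
#' @param labels Logical or factor; `TRUE`/`"positive"` = ALNM+.
#' @return List: `TP`, `FP`, `TN`, `FN`, `sensitivity`, `specificity`,
#'   `accuracy`, `F1`, `AUC`, `separation`.
#' @export
logistic_metrics <- function(embedding, labels) {
  y <- if (is.logical(labels)) labels else as.character(labels) == "positive"
  if (length(unique(y)) < 2L)
    gq_stop("glmqlmas_error_precondition", "both classes must be present")
  X <- cbind(1, as.matrix(embedding))
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(y), family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100L)))
  prob <- fit$fitted.values
  separation <- any(prob > 1 - 1e-8) && any(prob < 1e-8) &&
    all((prob > 0.5) == y)
  pred <- prob > 0.5
  TP <- sum(pred & y); FP <- sum(pred & !y)
  TN <- sum(!pred & !y); FN <- sum(!pred & y)
  r <- rank(prob)
  n1 <- sum(y); n0 <- sum(!y)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       accuracy = (TP + TN) / length(y),
       F1 = 2 * TP / (2 * TP + FP + FN),
       AUC = auc,
       separation = separation)
}

#' Metric curves over a range of principal components, before vs after
#' gene selection
#'
#' For each k, computes [logistic_metrics()] on the k-component PCA of the
#' full-gene matrix (`before`) and of the selected-gene matrix (`after`).
#'
#' @param logcpm_before,logcpm_after Genes x samples log-CPM matrices
#'   sharing the same samples.
#' @param labels Class labels (see [logistic_metrics()]).
#' @param k_range Component counts (default `2:20`).
#' @return Data frame with one row per k x stage: `k`, `stage`,
#'   `sensitivity`, `specificity`, `accuracy`, `F1`, `AUC`.
#' @export
pc_sweep <- function(logcpm_before, logcpm_after, labels, k_range = 2:20) {
  if (ncol(logcpm_before) != ncol(logcpm_after))
    gq_stop("glmqlmas_error_precondition", "matrices must share samples")
  rows <- lapply(k_range, function(k) {
    do.call(rbind, lapply(c("before", "after"), function(stage) {
      m <- if (stage == "before") logcpm_before else logcpm_after
      met <- logistic_metrics(pca_embed(m, k), labels)
      data.frame(k = k, stage = stage,
                 sensitivity = met$sensitivity, specificity = met$specificity,
                 accuracy = met$accuracy, F1 = met$F1, AUC = met$AUC,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher LDA1 projection of selected genes
#'
#' Projects samples onto the Fisher discriminant direction
#' \eqn{w = (S_{pooled} + \lambda I)^{-1}(\mu_+ - \mu_-)} with ridge
#' \eqn{\lambda = 10^{-6} \times} mean diagonal of the pooled
#' within-class covariance (pseudo-inverse fallback if still singular).
#' The separation fraction is the accuracy of the midpoint-threshold rule
#' on the 1-D projection.
#'
#' @param expr_topn Genes x samples matrix restricted to the selected
#'   (e.g. top-n MAS) genes.
#' @param labels Class labels; two classes with >= 2 samples each.
#' @param ridge Ridge multiplier of the mean covariance diagonal
#'   (default 1e-6).
#' @return List: `projection` (named 1-D scores), `direction`,
#'   `separation_fraction`.
#' @export
lda1 <- function(expr_topn, labels, ridge = 1e-6) {
  y <- if (is.logical(labels)) labels else as.character(labels) == "positive"
  X <- t(expr_topn)                        # samples x genes
  if (sum(y) < 2L || sum(!y) < 2L)
    gq_stop("glmqlmas_error_precondition", ">= 2 samples per class required")
  mu1 <- colMeans(X[y, , drop = FALSE]); mu0 <- colMeans(X[!y, , drop = FALSE])
  c1 <- stats::cov(X[y, , drop = FALSE]); c0 <- stats::cov(X[!y, , drop = FALSE])
  n1 <- sum(y); n0 <- sum(!y)
  Sp <- ((n1 - 1) * c1 + (n0 - 1) * c0) / (n1 + n0 - 2)
  lambda <- ridge * mean(diag(Sp))
  if (lambda == 0) lambda <- ridge
  A <- Sp + lambda * diag(ncol(X))
  w <- tryCatch(solve(A, mu1 - mu0), error = function(e) {
    gq_warn("singular pooled covariance; using pseudo-inverse")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*%
                                      (mu1 - mu0)) / sv$d[pos])
  })
  w <- as.numeric(w)
  proj <- as.numeric(X %*% w)
  names(proj) <- rownames(X)
  cut <- (mean(proj[y]) + mean(proj[!y])) / 2
  pred <- if (mean(proj[y]) > cut) proj > cut else proj < cut
  list(projection = proj, direction = w,
       separation_fraction = mean(pred == y))
}
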