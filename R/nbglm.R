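# Negative-binomial GLM fitting with a log link and offsets, vectorized
# across genes. The NB variance is mu + phi*mu^2 (dispersion phi; phi = 0 is
# Poisson). Fitting is iteratively reweighted least squares with Fisher
# weights w = mu/(1 + phi*mu); for the pipeline's designs (intercept-only
# reduced model, intercept + group full model) the per-gene weighted normal
# equations are solved in closed form simultaneously for all genes, with
# step halving on deviance increase. The common dispersion is estimated by
# maximizing the Cox-Reid adjusted profile likelihood.

#' Build the two-group design matrix
#'
#' Intercept plus ALNM-positive indicator; ALNM-negative is the reference
#' level so positive coefficients mean higher expression in ALNM+.
#'
#' @param annotation [sample_annotation()] with exactly two groups present
#'   (no missing status).
#' @return Numeric matrix, rows = samples, columns `(Intercept, groupALNM+)`.
#' @export
build_design <- function(annotation) {
  status <- as.character(annotation$alnm_status)
  if (any(status == "missing"))
    gq_stop("glmqlmas_error_precondition",
            "design requires samples with known ALNM status")
  if (length(unique(status)) != 2L)
    gq_stop("glmqlmas_error_precondition", "both ALNM groups must be present")
  X <- cbind("(Intercept)" = 1, "groupALNM+" = as.numeric(status == "positive"))
  rownames(X) <- annotation$sample_id
  X
}

# NB unit deviance summed per gene; y, mu are G x n matrices, phi scalar or
# per-gene (recycled down rows, matching R's column-major recycling).
nb_deviance <- function(y, mu, phi) {
  phi <- rep_len(phi, nrow(y))
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  d <- matrix(0, nrow(y), ncol(y))
  pois <- phi == 0
  if (any(pois))
    d[pois, ] <- 2 * (ylogy[pois, , drop = FALSE] -
                        (y[pois, , drop = FALSE] - mu[pois, , drop = FALSE]))
  if (any(!pois)) {
    yp <- y[!pois, , drop = FALSE]; mp <- mu[!pois, , drop = FALSE]
    pp <- phi[!pois]
    d[!pois, ] <- 2 * (ylogy[!pois, , drop = FALSE] -
                         (yp + 1 / pp) * log((1 + pp * yp) / (1 + pp * mp)))
  }
  rowSums(d)
}

# Full NB log-likelihood summed per gene (phi-dependent terms included,
# needed for profiling phi). phi may be scalar or per-gene.
nb_loglik <- function(y, mu, phi) {
  if (all(phi == 0))
    return(rowSums(stats::dpois(y, mu, log = TRUE)))
  inv <- 1 / phi
  ll <- lgamma(y + inv) - lgamma(inv) - lgamma(y + 1) +
    y * log(phi * mu / (1 + phi * mu)) - inv * log1p(phi * mu)
  rowSums(ll)
}

#' Fit negative-binomial GLMs for all genes
#'
#' Log-link IRLS with per-gene closed-form weighted least squares for the
#' intercept-only and intercept+group designs (a generic per-gene solver
#' covers other full-rank designs). Convergence requires both a relative
#' deviance change below `tol` and satisfied score equations
#' \eqn{|\sum_i x_{ij}(y_i-\mu_i)/(1+\phi\mu_i)| < 10^{-6}} per column.
#'
#' @param y Count matrix (genes x samples) or a single count vector.
#' @param design Design matrix (samples x coefficients), full column rank.
#' @param offset Offset vector (length samples) or matrix on the natural-log
#'   scale, typically `log(effective_library_size)`.
#' @param phi NB dispersion, scalar or per-gene.
#' @param tol Relative deviance convergence tolerance (default 1e-8).
#' @param maxit Iteration cap (default 100); non-convergence is flagged,
#'   not fatal.
#' @return List of class `nb_glm_fit`: `coefficients` (genes x p, natural
#'   log), `fitted` (mu), `deviance`, `df_residual`, `converged`,
#'   `iterations`, `design`, `offset`, `phi`.
#' @export
fit_nb_glm <- function(y, design, offset = 0, phi = 0, tol = 1e-8, maxit = 100L) {
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  G <- nrow(y); n <- ncol(y); p <- ncol(design)
  if (qr(design)$rank < p)
    gq_stop("glmqlmas_error_precondition", "design matrix is rank deficient")
  if (any(!is.finite(offset)))
    gq_stop("glmqlmas_error_precondition", "offsets must be finite")
  O <- if (is.matrix(offset)) offset else
    matrix(offset, G, n, byrow = length(offset) == n)
  phi <- rep_len(phi, G)

  # initial mean: library-share smoothed toward the gene mean
  mu <- pmax(y, 1 / 6)
  eta <- log(mu) - O
  beta <- matrix(0, G, p)
  # initialize beta by one unweighted LS solve of eta on design
  Xqr <- qr(design)
  beta <- t(qr.coef(Xqr, t(eta)))
  beta[!is.finite(beta)] <- 0
  eta <- beta %*% t(design)
  mu <- exp(eta + O)
  dev <- nb_deviance(y, mu, phi)
  iter_done <- integer(G)
  converged <- rep(FALSE, G)

  two_group <- p == 2L && all(design[, 1L] == 1) && all(design[, 2L] %in% c(0, 1))
  g2 <- if (two_group) design[, 2L] else NULL

  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)             # Fisher weights, G x n
    z <- eta + (y - mu) / mu             # working response minus offset part
    if (two_group) {
      a <- rowSums(w); b <- as.vector(w %*% g2)
      r1 <- rowSums(w * z); r2 <- as.vector((w * z) %*% g2)
      det <- b * (a - b)
      b1 <- (r1 - r2) / (a - b)
      b2 <- (a * r2 - b * r1) / det
      new_beta <- cbind(b1, b2)
    } else if (p == 1L) {
      x1 <- design[, 1L]
      new_beta <- matrix(rowSums(w * z * rep(x1, each = G)) /
                           rowSums(w * rep(x1^2, each = G)), ncol = 1L)
    } else {
      new_beta <- t(vapply(seq_len(G), function(g) {
        fit <- stats::lm.wfit(design, z[g, ], w[g, ])
        fit$coefficients
      }, numeric(p)))
    }
    bad <- !is.finite(rowSums(new_beta))
    if (any(bad)) new_beta[bad, ] <- beta[bad, , drop = FALSE]

    new_eta <- new_beta %*% t(design)
    new_mu <- exp(new_eta + O)
    new_dev <- nb_deviance(y, new_mu, phi)

    # step halving only on appreciable divergence; round-off-level
    # fluctuations must pass or the final Newton steps stall
    for (h in seq_len(8L)) {
      worse <- which(new_dev > dev + 1e-6 * (abs(dev) + 1))
      if (!length(worse)) break
      new_beta[worse, ] <- (new_beta[worse, , drop = FALSE] +
                              beta[worse, , drop = FALSE]) / 2
      new_eta[worse, ] <- new_beta[worse, , drop = FALSE] %*% t(design)
      new_mu[worse, ] <- exp(new_eta[worse, , drop = FALSE] +
                               O[worse, , drop = FALSE])
      new_dev[worse] <- nb_deviance(y[worse, , drop = FALSE],
                                    new_mu[worse, , drop = FALSE], phi[worse])
    }

    rel <- abs(new_dev - dev) / (abs(dev) + 0.1)
    beta <- new_beta; eta <- new_eta; mu <- new_mu
    prev_dev <- dev; dev <- new_dev

    score <- abs(((y - mu) / (1 + phi * mu)) %*% design)
    ok <- rel < tol & apply(score, 1L, max) < 1e-6
    newly <- ok & !converged
    iter_done[newly] <- it
    converged <- converged | ok
    if (all(converged)) break
  }
  iter_done[!converged] <- maxit
  if (!all(converged))
    gq_warn(paste(sum(!converged), "gene fits did not converge"))

  beta <- matrix(as.numeric(beta), nrow = G,
                 dimnames = list(rownames(y), colnames(design)))
  dimnames(mu) <- dimnames(y)
  names(dev) <- rownames(y)
  structure(list(coefficients = beta, fitted = mu, deviance = dev,
                 df_residual = n - p, converged = converged,
                 iterations = iter_done, design = design, offset = O,
                 phi = phi),
            class = "nb_glm_fit")
}

#' Estimate the common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' For candidate dispersion phi, every gene is refitted and the summed
#' adjusted profile log-likelihood
#' \eqn{\sum_g [\ell_g(\phi) - \frac12 \log\det(X^T W_g X)]} is maximized
#' over \eqn{\log\phi} on `[1e-8, 10]` by golden-section/parabolic search.
#' Falls back to a method-of-moments estimate if the search fails.
#'
#' @param counts Count matrix (genes x samples).
#' @param design Design matrix.
#' @param offset Offset vector/matrix (natural log scale).
#' @param subset_genes Optional cap on the number of genes used (evenly
#'   spaced by abundance) to bound cost on large matrices; `Inf` uses all.
#' @return Scalar dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, design, offset = 0,
                                       subset_genes = Inf) {
  if (ncol(counts) - ncol(design) < 2)
    gq_stop("glmqlmas_error_precondition", "not enough residual df")
  y <- counts
  if (is.finite(subset_genes) && nrow(y) > subset_genes) {
    ord <- order(rowMeans(y))
    idx <- ord[unique(round(seq(1, nrow(y), length.out = subset_genes)))]
    y <- y[sort(idx), , drop = FALSE]
  }
  apl <- function(log_phi) {
    phi <- exp(log_phi)
    fit <- suppressWarnings(fit_nb_glm(y, design, offset, phi, tol = 1e-6,
                                       maxit = 50L))
    ll <- nb_loglik(y, fit$fitted, phi)
    w <- fit$fitted / (1 + phi * fit$fitted)
    # log det(X'WX) for the pipeline's designs
    if (ncol(design) == 2L && all(design[, 1] == 1)) {
      g2 <- design[, 2L]
      a <- rowSums(w); b <- as.vector(w %*% g2); d <- as.vector(w %*% g2^2)
      ld <- log(pmax(a * d - b^2, 1e-300))
    } else if (ncol(design) == 1L) {
      ld <- log(pmax(rowSums(w * rep(design[, 1L]^2, each = nrow(y))), 1e-300))
    } else {
      ld <- vapply(seq_len(nrow(y)), function(g) {
        determinant(crossprod(design, design * w[g, ]))$modulus
      }, numeric(1))
    }
    sum(ll - 0.5 * ld)
  }
  opt <- tryCatch(
    stats::optimize(apl, interval = log(c(1e-8, 10)), maximum = TRUE,
                    tol = 1e-4),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    gq_warn("dispersion profile search failed; using method-of-moments fallback")
    sf <- exp(if (is.matrix(offset)) colMeans(offset) else
      rep_len(offset, ncol(y)))
    sf <- sf / mean(sf)
    ys <- t(t(y) / sf)
    m <- rowMeans(ys); v <- apply(ys, 1L, stats::var)
    phi_g <- (v - m) / m^2
    return(max(1e-8, min(10, stats::median(phi_g[is.finite(phi_g)], na.rm = TRUE))))
  }
  exp(opt$maximum)
}
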