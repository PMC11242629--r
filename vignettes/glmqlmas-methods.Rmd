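---
title: "Methods: quasi-likelihood differential expression and Magnitude-Altitude ranking for nodal-metastasis cohorts"
author: "glmqlmas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasi-likelihood differential expression and Magnitude-Altitude ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmqlmas)
```

## The problem

Bulk RNA-seq counts from tumor cohorts are discrete, overdispersed, and
sequenced to uneven depths with sample-specific transcriptome composition.
`glmqlmas` implements a complete analysis chain for ranking genes
associated with a two-group phenotype — axillary lymph node metastasis
(ALNM+ vs ALNM−) in breast cancer is the motivating design, with 65
node-negative and 42 node-positive untreated samples — and for assessing
how well the selected genes separate the two groups. Every statistical
stage is implemented from its defining formulas and validated against
independent oracles; the synthetic-data module generates cohorts with
known ground truth so the whole chain can be tested end to end without
access to patient data.

## Count model

Counts $y_{gi}$ for gene $g$ in sample $i$ are modelled as negative
binomial with mean $\mu_{gi}$ and variance
$\mu_{gi} + \phi\,\mu_{gi}^2$. The dispersion $\phi \ge 0$ captures
biological variability beyond Poisson noise ($\phi = 0$ recovers the
Poisson). The mean follows a log-link GLM

$$\log \mu_{gi} = o_i + \beta_{g0} + \beta_{g1} x_i,$$

where $x_i$ indicates ALNM+ (ALNM− is the reference level, so positive
coefficients mean higher expression in node-positive tumors) and the
offset $o_i = \log(\text{effective library size}_i)$ carries the
normalization. The reported log2 fold change is $\beta_{g1}/\ln 2$.

### TMM normalization

Between-sample scale factors are computed by the trimmed mean of M-values.
For a test/reference library pair, genes with positive counts in both
samples contribute

$$M_g = \log_2 \frac{y_{gt}/N_t}{y_{gr}/N_r}, \qquad
  A_g = \tfrac12 \log_2 \left( \frac{y_{gt}}{N_t}\,\frac{y_{gr}}{N_r} \right),$$

the top and bottom 30% by $M$ and 5% by $A$ are discarded (intersection of
survivors), and the factor is $2$ raised to the precision-weighted mean of
the surviving $M_g$, with inverse asymptotic-variance weights
$w_g^{-1} = (N_t-y_{gt})/(N_t y_{gt}) + (N_r-y_{gr})/(N_r y_{gr})$. The
reference sample is the one whose upper quartile of library-scaled counts
is closest to the mean upper quartile; factors are rescaled to geometric
mean 1. Trim fractions and the reference rule follow the method's
published description and are exposed as arguments. Zero counts in either
member of a pair are excluded (the log-ratio is undefined), never imputed.
One nuance worth knowing: multiplying one library's counts and size by a
constant leaves every $M_g$ unchanged but shifts the precision weights, so
the factor is stable only to a fraction of a percent under pure depth
scaling of a single library — an exact invariance is not implied by the
defining formula.

Log-CPM values used by the diagnostics are depth-stabilized:
$p_i = p\,L_i/\bar L$ with prior count $p = 1$ and effective sizes $L_i$,
and $\log_2\!\big(10^6 (y_{gi} + p_i)/(L_i + 2p_i)\big)$, which is strictly
monotone in the count.

### Fitting and the quasi-likelihood F-test

Each gene is fitted by iteratively reweighted least squares with Fisher
weights $\mu/(1+\phi\mu)$; for the pipeline's two designs (intercept-only
and intercept + group) the per-gene normal equations are solved in closed
form simultaneously for all genes, which keeps a 2,000-gene cohort fit
around a second. Convergence demands a relative deviance change below
1e-8 *and* score equations satisfied to 1e-6; step halving guards against
divergence but ignores round-off-level deviance fluctuations, which would
otherwise stall the final Newton steps.

The working dispersion is a single common $\phi$ maximizing the Cox-Reid
adjusted profile likelihood $\sum_g [\ell_g(\phi) - \tfrac12 \log\det
(X^\top W_g X)]$ over $\log\phi \in [\log 10^{-8}, \log 10]$. Gene-wise
variability is then carried by the quasi-likelihood layer: raw
quasi-dispersions $s^2_g = D_g/d_g$ (residual deviance over residual df)
are moderated toward a prior $(d_0, s^2_0)$ estimated by moment-matching
the spread of $\log s^2_g$ against its theoretical scaled-F value
(trigamma inversion), giving

$$s^2_{g,\mathrm{post}} = \frac{d_0 s^2_0 + d_g s^2_g}{d_0 + d_g}.$$

When the observed spread is *smaller* than the theoretical sampling
spread, the prior df is infinite and all moderated values collapse to the
prior, which is then taken as the geometric mean of the raw dispersions so
that an all-equal input is an exact fixed point of the moderation. The
group effect is tested with
$F_g = \big((D_{\mathrm{red},g}-D_{\mathrm{full},g})/1\big)/s^2_{g,\mathrm{post}}$
against $F(1,\,d_0+d_g)$. p-values are clamped at 1e-300 so downstream
log10 transforms stay finite. Deviance-based (not Pearson) dispersions are
used, and residual df are not adjusted for fitted zeros — a documented
simplification; a trended or gene-wise working dispersion is out of scope.

## Magnitude-Altitude Score

Each gene passing the significance gate (adjusted $p <$ 0.05 by default)
and the effect gate ($|\mathrm{log2FC}|$ strictly above the threshold,
default 1) receives

$$\mathrm{MAS}_g = |\log_2 FC_g|^{M}\,\cdot\,|\log_{10} p^{\mathrm{adj}}_g|^{A},$$

with $M = A = 1$ by default so effect size and statistical strength carry
equal weight. Genes are ranked by MAS descending with deterministic ties
(larger $|\mathrm{log2FC}|$, then gene ID — an artifact choice, stated
because any tie rule is arbitrary). Because the score does not depend on
the gate, the top-$k$ set at threshold $t$ is exactly the top-$k$ of the
threshold-0 ranking restricted to genes passing $t$; the threshold sweep
(0–7) verifies this ranking stability, and the gate can equally use raw or
Bonferroni-adjusted p-values, which produce nested significant sets.

## Balanced resampling consistency

To guard against the group imbalance (65 vs 42), the majority group is
subsampled to the minority size and the *entire* analysis — all-zero-gene
removal, TMM, dispersion estimation, GLM fits, F-tests, and BH correction
within the iteration — is re-run on each balanced cohort (iteration $i$
uses seed $\mathrm{base} + i$, so iterations are order-independent and
individually reproducible). Per gene and per $|\mathrm{log2FC}|$ threshold
(1 through 6), the iterations in which it is BH-significant up or down are
counted. A biomarker must recur in at least half the iterations in one
direction with zero opposite-direction occurrences — the strict reading of
an unequivocal trend; a laxer reading (tolerating a few opposite
occurrences) is exposed as `allow_opposite_count`. Genes recurring in
every iteration form the "strongest" tier. The full-cohort MAS list and
the resampling-qualified list are finally intersected per direction,
preserving MAS order.

## Over-representation analysis

Significant-gene lists are tested against GMT collections with the
hypergeometric upper tail $P(X \ge k)$ (observed overlap included),
$X \sim \mathrm{Hypergeom}(N, K, n)$, and BH q-values across the tested
collection. The universe is the analyzed genes intersected with the union
of collection members — the conservative ORA convention, chosen because
nothing narrower is defensible without annotation provenance. Sets are
size-gated (5–2,000 within the universe) before testing. This is overlap
ORA, not the ranked running-sum statistic: the reported per-set overlap
genes are the object of interest here, and depletion is deliberately not
tested.

## Separability diagnostics

These analyses illustrate class structure; they are resubstitution fits,
not validated predictive models, and are labelled as such in outputs.

* **PCA + logistic sweep.** Gene-standardized log-CPM is projected onto
  $k = 2\ldots20$ principal components (sign-fixed so each component's
  largest-magnitude loading is positive); an unregularized logistic
  regression (Newton, tolerance 1e-10, 100 iterations, perfect separation
  flagged) is fitted on the same samples, and sensitivity, specificity,
  accuracy, F1 and rank-sum AUC are reported for the full gene matrix
  ("before" selection) and the MAS-selected matrix ("after").
* **LDA1.** The Fisher direction
  $w = (S_{\mathrm{pooled}} + \lambda I)^{-1}(\mu_+ - \mu_-)$ with ridge
  $\lambda = 10^{-6} \times$ mean diagonal of $S_{\mathrm{pooled}}$
  (pseudo-inverse fallback if still singular) projects the top-$n$ MAS
  genes ($n = 20\ldots100$) to one dimension; the separation fraction is
  the accuracy of the midpoint-threshold rule.
* External 2-D embeddings (e.g., precomputed t-SNE coordinates) can be fed
  to `logistic_metrics()` directly; t-SNE itself is intentionally not
  implemented.

## The synthetic cohort generator

`sim_config()` defaults mirror the target study design: a 60,660-gene
annotated universe with 19,938 protein-coding genes and 65 + 42 samples.
Counts are NB with gene baselines drawn log-uniformly over $e^1$–$e^8$
(spanning near-zero to abundant genes, which exercises TMM trimming and
count discreteness), log-normal library-depth factors (sdlog 0.3, a
realistic bulk RNA-seq depth spread), dispersion 0.1 (biological CV
$\approx$ 0.32, typical of human tumor cohorts), and a planted fraction of
truly differential protein-coding genes with known signed log2 fold
changes. Optional composition bias expresses a small gene fraction at 20×
baseline in one group only — the failure mode TMM corrects and library
size alone does not. Extra samples with missing nodal status or prior
treatment exercise the cohort filter. One master seed feeds fixed
per-component sub-streams, so gene parameters, depths and counts are
independently reproducible.

What the generator does *not* emulate: batch effects, correlated genes,
isoform structure, trended mean–dispersion relationships, or read-level
artifacts. Passing tests therefore demonstrate correctness of the
statistical machinery under its own model assumptions, not robustness to
every pathology of real cohorts.

### Problem sizes used in the tests

The package's own validation runs at a scale chosen to exercise the
study design faithfully while keeping the suite fast: null-calibration
and power simulations use 2,000 genes (21 vs 21 and 65 vs 42); the
resampling recovery check runs 50 balanced iterations (a scaled stand-in
for the 500-iteration production setting, with the qualification rule
scaled to 25/50); the end-to-end run uses 2,000 genes × 107 retained
samples. Two deliberately tuned fixtures: the resampling fixture draws
baselines from $e^4$–$e^7$ so its single planted gene has the adequate
sequencing depth the recovery property presumes, and the before/after
selection comparison plants sparse, moderate signal (0.5% of genes at
$|\mathrm{log2FC}| = 2$, dispersion 0.4) so that the full-gene principal
components do not already saturate resubstitution metrics — with ten
components and ~100 samples a logistic fit separates strongly-signalled
synthetic data perfectly in both arms, which would make the comparison
vacuous.

## Numerical choices and degenerate inputs

* p-value floor 1e-300 (finite log10 downstream).
* Quasi-dispersions floored at 1e-8 before logs (exact-zero deviances).
* TMM falls back to factor 1 with a warning when no genes survive
  trimming or the weighted mean is non-finite; a sample against itself is
  exactly 1.
* Dispersion search falls back to a method-of-moments estimate if the
  profile optimization fails.
* All-zero genes are removed before fitting (inestimable); no
  abundance-based expression filter is applied beyond that, matching a
  design in which essentially all coding genes are analyzed.
* The GLM flags non-convergence per gene rather than failing the run.
* Ranking and enrichment ties are broken deterministically (documented
  above), so outputs are byte-reproducible for a fixed seed.

## Known limitations

* Single two-level factor designs only; no covariates, no multi-factor
  contrasts (df of the test is fixed at 1).
* Common working dispersion (no trend over abundance); gene-wise
  variability enters only through the QL layer.
* Resubstitution diagnostics overstate absolute separability by
  construction; only the before/after *contrast* is meaningful.
* ORA treats gene sets as flat lists; no ontology topology, no depletion.
* The generator's independence across genes understates correlation-driven
  false-discovery clustering seen in real tumors.

## A worked example

```{r example, eval = FALSE}
sim <- generate_cohort(sim_config(
  n_genes = 2000, n_coding = 1700, group_sizes = c(65, 42),
  de_fraction = 0.05, dispersion = 0.1, seed = 1))
sets <- generate_gene_sets(sim$truth$gene_id, n_sets = 30,
                           planted_set_from = sim$truth, seed = 2)
res <- run_pipeline(sim$counts, sim$samples, sim$genes, gene_sets = sets,
                    config = run_config(seed = 1, resampling_R = 50,
                                        consistency_min = 25))
head(res$ranked)        # MAS-ranked gene table
head(res$biomarkers)    # resampling-qualified biomarkers
head(res$enrichment)    # hypergeometric ORA results
```
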