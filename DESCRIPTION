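Package: glmqlmas
Title: Differential Expression and Biomarker Ranking for Lymph Node
    Metastasis via Quasi-Likelihood GLMs and Magnitude-Altitude Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for ranking genes associated with a
    two-group phenotype (axillary lymph node metastasis, ALNM+/ALNM-) from
    bulk RNA-seq counts. Implements trimmed-mean-of-M-values (TMM)
    normalization, negative-binomial generalized linear models with
    quasi-likelihood F-tests, the Magnitude-Altitude Score (MAS) composite
    gene ranking, balanced-resampling directional-consistency biomarker
    selection, hypergeometric gene-set over-representation analysis, and
    low-dimensional separability diagnostics (PCA + logistic regression,
    Fisher LDA1). Ships a synthetic-count-data generator with planted
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
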