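Package: methmix
Title: Bayesian Clustering and Imputation of Single-Cell Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint clustering and imputation for sparse single-cell bisulfite
    sequencing data. Cells are clustered genome-wide with a finite Dirichlet
    mixture model whose components are smooth per-region methylation profiles
    (probit regression on radial basis functions), fitted by mean-field
    variational inference with automatic pruning of empty components, or by
    Gibbs sampling. Held-out CpG methylation states are imputed from the
    posterior predictive density. Includes the standard comparator methods
    (per-region methylation rates, an intercept-only mixture, a Gaussian
    mixture on M-values, and independently fitted probit profiles), a
    synthetic-data generator with cluster-structured latent profiles, and
    imputation and clustering metrics (AUC, F-measure, precision-recall
    curves, adjusted Rand index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
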