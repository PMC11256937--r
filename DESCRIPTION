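Package: celldpm
Title: Adaptive Clustering of Single-Cell RNA-Seq Data with a
    DPMM-Coupled Autoencoder
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@celldpm.org",
           role = c("aut", "cre"))
Description: Adaptive clustering of single-cell RNA-seq UMI count matrices.
    A fully connected autoencoder with a Poisson reconstruction likelihood
    learns a low-dimensional representation that is jointly shaped by a
    Dirichlet process mixture model (truncated stick-breaking prior with
    Normal-Wishart components, fitted by variational inference), so that the
    number of clusters is inferred from the data rather than specified.
    Includes the preprocessing recipe (library-size normalization, log
    transform, variance-stabilized highly-variable-gene selection, per-gene
    scaling), clustering evaluation metrics (NMI, ARI, scaled silhouette,
    deviation ratio), synthetic count and latent-mixture simulators with
    known ground truth, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    cluster,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    data.table,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
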