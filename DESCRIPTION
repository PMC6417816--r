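Package: latentbench
Title: Benchmarking Variational-Autoencoder Latent Spaces for Single-Cell
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates labeled single-cell RNA-seq count matrices with a
    gamma-Poisson hierarchy (cell groups, expression outliers, library-size
    variation, optional logistic dropout), embeds them with a Tybalt-style
    variational autoencoder and standard baselines (PCA, t-SNE, UMAP), and
    scores every latent space with three protocols: repeated k-means against
    ground-truth labels (NMI/ARI), nested cross-validated k-nearest-neighbour
    classification, and average silhouette width. A grid-search harness
    sweeps VAE hyperparameters (depth, learning rate, batch size, epochs,
    first hidden width) and extracts best/worst combinations, quantifying how
    strongly embedding quality depends on tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    Rtsne,
    class,
    irlba,
    jsonlite,
    stats,
    utils,
    uwot,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
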