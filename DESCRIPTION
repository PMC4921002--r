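Package: mdcall
Title: Genotype Calling for Two-Channel SNP Array Intensities with
    Gaussian and Dirichlet Process Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genotypes (AA, AB, BB) from two-channel SNP-array
    fluorescence intensities. Common SNPs are called with a per-SNP
    three-component bivariate Gaussian mixture fitted by EM; rare SNPs are
    called with a Dirichlet Process Gaussian mixture fitted by collapsed
    Gibbs sampling, so the number of occupied genotype clusters is inferred
    from the data; extremely rare SNPs are called jointly with an
    automatically selected good-quality reference SNP, which anchors
    sparsely populated minor clusters. SNPs are routed between the three
    models by minor allele frequency and per-cluster sample size. Includes
    per-call posterior-rate quality scores, call-rate, concordance and
    accuracy metrics, Hardy-Weinberg equilibrium tests, and a synthetic
    BeadArray intensity simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
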