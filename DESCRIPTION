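Package: pleioscan
Title: Testing Pleiotropy Versus Separate QTL in Multiparental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-ratio test of pleiotropy versus separate quantitative
    trait loci (QTL) for a pair of traits in multiparental populations such as
    Diversity Outbred mice. Fits a matrix-variate linear mixed model with a
    Kronecker-structured covariance (polygenic kinship plus residual), performs
    a two-dimensional two-QTL scan over a genomic interval on founder-allele
    probabilities, visualizes profile LOD traces, and calibrates the test
    statistic with a parametric bootstrap. Includes a synthetic multi-founder
    genotype generator and type-I-error and power simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tools,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
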