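Package: ssqtl
Title: QTL Mapping with Single-Step GBLUP and Bayes C in Simulated Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of livestock populations with
    contrasting levels of linkage disequilibrium, and genome-wide association
    analysis of a low-heritability sex-limited trait on the simulated data.
    Implements pedigree and genomic relationship matrices, single-step GBLUP
    with iterative SNP weighting (WssGBLUP), a Bayes C Gibbs sampler with a
    near-fixed inclusion fraction, and window-based QTL detection statistics
    that quantify how much phenotypic information from non-genotyped animals
    contributes to QTL mapping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
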