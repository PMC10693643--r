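Package: splitABC
Title: Approximate Bayesian Computation for Two-Population Clean-Split
    Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the split time and effective population size histories of
    two populations under a clean-split coalescent model by Approximate
    Bayesian Computation. Provides the demographic model and priors, a
    coalescent simulator bridge, a genotype error model, a fixed registry of
    46 summary statistics including identity-by-descent (IBD) and
    runs-of-homozygosity (ROH) haplotype statistics, rejection sampling with
    neural-network or local-linear regression adjustment on logit-transformed
    parameters, holdout validation with error and coverage reporting, and
    standalone cohort statistics (shared f2 alleles, one-tailed permutation
    tests on pairwise IBD sharing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    nnet,
    yaml,
    jsonlite,
    data.table,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
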