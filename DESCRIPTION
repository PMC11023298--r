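Package: pgsdiff
Title: Bayesian Assessment of Population Differences in Polygenic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and tests differences in mean genetic risk between two
    populations from GWAS summary statistics, accounting for the uncertainty
    that the finite GWAS training sample induces in polygenic-score weights.
    Provides analytic spike-and-slab (point-normal) posterior moments for
    per-SNP effects, the posterior distribution of the log relative risk
    between populations under SNP independence, a closed-form variance under
    the infinitesimal model, a calibrated Wald test together with the naive
    t-test comparator, a Hudson-style Fst estimator, and a summary-statistic
    simulator (Balding-Nichols allele frequencies, point-normal effects) with
    drivers for posterior-uncertainty, type-1-error, power and bias/MSE
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
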