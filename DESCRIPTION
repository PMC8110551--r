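Package: spebf
Title: Semi-Parametric Empirical Bayes Factors for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("pkg", "maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayes factor analysis of genome-wide association study (GWAS)
    summary statistics under a two-group hierarchical mixture model.
    Implements Wakefield's approximate Bayes factor (ABF) with a normal
    N(0, W) effect-size prior, and a semi-parametric empirical Bayes factor
    (SP-EBF) whose effect-size prior is a nonparametric discrete distribution
    estimated from the data by a smoothing-and-roughening EM algorithm,
    together with the estimated non-null proportion. Provides per-SNP
    posterior null probabilities, Bayesian decision rules, significance
    rankings comparing P value, ABF and SP-EBF, a calibrated simulator of
    case-control summary statistics, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
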