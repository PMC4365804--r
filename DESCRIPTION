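Package: countHDP
Title: Clustering and Differential Expression of Digital Gene Expression
    Data via Hierarchical Dirichlet Process Mixtures
Version: 0.1.0
Authors@R:
    person("countHDP", "Developers", email = "counthdp@example.org",
           role = c("aut", "cre"))
Description: Model-based clustering of digital gene expression count data
    (RNA-seq, CAGE, SAGE) with a hierarchical Dirichlet process mixture of
    negative binomial distributions, and differential expression analysis
    derived from the clustering.  Gene- and condition-specific log-fold-
    changes are shared within and across sample groups through a two-level
    Dirichlet process prior; posterior inference uses a truncated blocked
    Gibbs sampler.  Differential expression between two groups is measured
    by the posterior probability that a gene occupies the same fold-change
    cluster in both groups, which yields a conditional false discovery rate
    without P values or multiplicity corrections.  Includes median-of-ratios
    normalisation, posterior similarity matrices for genes and for sample
    groups, consensus clustering, a synthetic-data generator for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse,
    ape,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
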