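Package: mamut
Title: Mutation-Rate Estimation and Spectra for Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("MA", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for bacterial mutation-accumulation
    (MA) experiments under serial single-colony bottlenecking. Implements
    post-calling variant filtering (depth/quality thresholds, ancestral
    subtraction, cross-line consensus removal, small-indel size rule, windowed
    structural-variant deduplication across callers), per-line mutation-rate
    estimation with Z-score outlier exclusion and group comparisons,
    serial-transfer effective population sizes by harmonic mean,
    pyrimidine-centred 96-class trinucleotide mutation spectra,
    non-negative matrix factorization of spectra into mutation patterns with
    cophenetic rank selection, Luria-Delbruck fluctuation-test maximum
    likelihood estimation of mutation rates, and zero-intercept regression of
    genomic divergence on generations. A synthetic-data module generates every
    input the pipeline consumes so all stages are testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
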