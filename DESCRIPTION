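Package: mqtlshare
Title: Cross-Ancestry cis-mQTL Sharing, Fine Mapping and Pleiotropy Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the genetic control of DNA methylation across
    ancestries from cohort-level cis-mQTL summary statistics. Implements
    per-cohort cis-window association scans on rank-transformed methylation
    residuals, fixed-effects inverse-variance-weighted meta-analysis within
    ancestry, an error-aware estimator of the correlation of QTL effect sizes
    between datasets (r_b) with jackknife standard errors, LD-block
    construction from reference panels, a hierarchical classification of
    shared versus ancestry-specific mQTLs, stepwise approximate conditional
    analysis from summary statistics, single- and cross-ancestry
    single-causal-variant fine mapping with 95% credible sets and a
    sample-size simulation, and summary-based Mendelian randomization with
    the HEIDI heterogeneity filter. A two-population Balding-Nichols
    genotype and methylation simulator with known ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
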