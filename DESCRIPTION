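Package: crossgwas
Title: Cross-Phenotype GWAS Analysis with Shared Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-phenotype analysis of case-control GWAS summary
    statistics from overlapping-control designs: reading, writing and
    cross-cohort allele harmonization of summary-statistic tables; Bayesian
    classification of lead-variant effects as null, shared (fixed or
    correlated), single-phenotype or phenotype-subset, with adjustment for
    the estimate correlation induced by a shared control pool; two-cohort
    heterogeneity testing and inverse-variance-weighted fixed-effect
    meta-analysis with a replication classification; distance/r2 locus
    clumping and cross-phenotype effect matrices; single-causal-variant
    approximate-Bayes-factor fine-mapping with 95% credible sets;
    credible-set colocalization via the causal posterior probability (CLPP)
    and causal posterior agreement (CLPA) metrics; a minimal LD score
    regression heritability/genetic-correlation estimator with
    threshold-based phenotype grouping; and a synthetic-data generator
    (LD-blocked genotypes, multi-phenotype logistic outcomes over a single
    shared control pool, direct summary-statistic simulation) so the whole
    pipeline can be exercised end to end without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
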