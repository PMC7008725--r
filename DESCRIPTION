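Package: pleiocca
Title: Multivariate Pleiotropy Analysis of GWAS Summary Statistics via
    Canonical Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cross-trait pleiotropy from genome-wide association
    study (GWAS) summary statistics alone. Per-disease regression
    coefficients from independent cohorts are harmonized to a common
    allele convention, standardized to the correlation scale, and
    combined with a reference-panel linkage-disequilibrium (LD)
    structure into a full genotype-phenotype covariance matrix, which
    is shrunk to positive semidefiniteness when required and entered
    into canonical correlation analysis at the single-SNP and gene
    level. Gene-level hits are refined by an LD-aware Monte-Carlo
    sum-of-chi-squares gene-based test per disease, Bonferroni
    thresholds, and an intersection filter producing pleiotropic gene
    calls with multi-disease and novelty annotation. A synthetic-data
    module simulates multi-cohort GWAS with blockwise LD and known
    pleiotropic architecture, plus an individual-level CCA oracle, so
    the whole pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
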