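Package: robpgs
Title: Robust Polygenic Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and corrects common misspecifications in GWAS summary
    statistics (heterogeneous per-variant sample sizes, imputation INFO,
    allele and frequency errors, mismatched LD references) and derives
    polygenic scores that are robust to them. Implements per-variant
    genotype-standard-deviation inference from summary statistics,
    sample-size imputation, INFO-based corrections, standard-deviation
    quality control, a windowed sparse LD reference with optimal
    independent-block splitting and a compact on-disk format, an
    elastic-net summary-statistics solver (lassosum2) with per-variant
    penalty factors, and a spike-and-slab Gibbs sampler (LDpred2-style
    infinitesimal, grid and auto modes) with low-heritability grids,
    off-diagonal LD shrinkage and sign-jump control. A synthetic-data
    module generates genotype panels with blocky LD, imputed dosages with
    target INFO, phenotypes with set heritability, and GWAS summary
    statistics under the misspecification scenarios, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
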