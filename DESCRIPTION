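Package: polygee
Title: Polygenic-Effect and Confounding Estimation from GWAS Summary
    Statistics via Generalized Estimating Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates confounding inflation and polygenic effects from
    genome-wide single-variant association test statistics.  Fits a
    gamma-type marginal model for chi-squared statistics, E[x2] =
    beta1 + C_study * l * beta2 with Var(x2) = phi * E[x2]^2, by
    generalized estimating equations over 1 centimorgan linkage-
    disequilibrium (LD) blocks, using reference-panel LD matrices as
    working correlations and a sandwich variance corrected for
    correlation between adjacent blocks.  Includes study-design
    constants for case-control, quantitative, family-based (FBAT) and
    mixed designs, LD-score and band LD-matrix computation from phased
    haplotypes with a genetic map, an explicit weighted-least-squares
    LD Score regression comparator, summary-statistic filtering, and a
    simulation harness with a synthetic mosaic-haplotype generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
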