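Package: mloyr
Title: Mosaic Loss of Chromosome Y: Copy-Number Calling, Single-Cell
    Association and Mendelian Randomisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mosaic loss of chromosome Y (mLOY) from whole-genome
    sequencing read depth via the MSY/autosome copy-number ratio and a
    cohort mean-minus-SD grouping rule, calls mLOY per cell from
    single-cell chrY/autosome read ratios with logistic-regression
    association against disease, lineage and cell identity, and provides
    a bidirectional two-sample Mendelian randomisation suite (IVW with
    multiplicative random effects, MR-Egger, weighted median, MR-Lasso,
    MR-PRESSO) with instrument selection, LD clumping, harmonisation,
    heterogeneity statistics and leave-one-out sensitivity analysis.
    Includes seeded synthetic-data generators with known ground truth for
    every pipeline input, plus clinical cohort rules (disease-progression
    classification, age propensity matching, nonparametric group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    GenomicRanges,
    IRanges,
    Matrix,
    Rsamtools,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
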