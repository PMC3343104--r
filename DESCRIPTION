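Package: flychc
Title: Cuticular Hydrocarbon Profile Statistics, Two-Choice Preference
    Scoring, and Relative Expression Analysis for Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studies linking physiology to
    cuticular hydrocarbon (CHC) pheromone profiles and sexual
    attractiveness in Drosophila.  Provides relative quantitation of
    GC/MS and LDI-MS peak-intensity tables with per-compound two-factor
    ANOVA and Holm-Bonferroni correction, chain-length and
    cross-manipulation delta-profile regressions, correlation-matrix PCA
    followed by ANCOVA, dwell-time scoring of two-choice courtship
    trials from trajectories or bout lists, Wilcoxon signed-rank and
    replicate-stratified permutation tests of preference against the 50%
    null, and delta-delta-Ct relative expression analysis with
    replicate-based z-tests.  Seeded synthetic-data generators with
    known ground truth support calibration and parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
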