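Package: thermoflex
Title: Thermogenic Flexibility and Thermal Heterogeneity in Junco Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for studying thermogenic flexibility in
    dark-eyed juncos and their congeners. Converts open-flow heliox
    respirometry traces into summit metabolic rates (M_sum) with baseline
    drift correction and quality control; builds acclimatization-window
    environmental predictors from daily weather tables; fits and ranks
    field reaction-norm models by AIC; performs SNP filtering,
    genotype imputation, PCA, conditioned redundancy analysis with
    permutation tests and variance partitioning, and Weir-Cockerham F_ST;
    runs partial Mantel comparisons of genetic, environmental and
    geographic distances; and analyzes common-garden acclimation
    experiments with a Gibbs-sampled Bayesian linear mixed model whose
    population random effect carries an F_ST-derived covariance. A
    synthetic-data module generates every input with known ground truth
    so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
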