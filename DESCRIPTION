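Package: n15trace
Title: Mass-Balance and Nitrogen-Transfer Analysis for Split-Root 15N Tracer Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for split-root 15N-labelling experiments in
    legume-grass systems: delta15N and atom-fraction scale conversions,
    atom-fraction-excess mass balance, percent retention of an applied
    15N-urea dose across plant and soil pools, plant-to-plant and
    plant-to-soil-protein nitrogen transfer (P_transfer, N_transfer, Ndft),
    compound-specific amino-acid 15N stable-isotope probing over the total
    hydrolysable amino-acid (THAA) pool with internal-standard quantification
    and recovery correction, treatment comparison statistics (one-way ANOVA
    with step-down Holm-Sidak multiple comparisons, Welch t-tests, normality
    and variance-homogeneity checks), and a synthetic-experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
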