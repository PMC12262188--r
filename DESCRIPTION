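Package: echodecorr
Title: Three-Dimensional Ultrasound Echo Decorrelation Imaging and
    Closed-Loop Ablation Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of three-dimensional ultrasound echo
    decorrelation imaging for monitoring and closed-loop control of
    radiofrequency thermal ablation. Generates seeded synthetic paired
    complex IQ echo volumes on a phased-array sector geometry with a known,
    growing heat-induced decoherence region; scan-converts sector volumes to
    an isotropic Cartesian grid and computes instantaneous and cumulative
    combined-normalized echo decorrelation maps; runs a threshold-based
    feedback controller that classifies trials as uncontrolled, successfully
    controlled or unsuccessfully controlled; quantifies ablation zones
    (volume, rate, Dice overlap, histology sectioning round trip); assesses
    voxelwise ablation prediction with ROC and precision-recall analysis,
    minimum-achievable-AUPR correction and effective-sample-size-scaled
    significance tests; and provides group-level outcome statistics
    (chi-squared success-rate comparisons, assumption screens, three-factor
    ANOVA or Kruskal-Wallis with post hocs, and linear regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
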