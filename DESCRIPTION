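Package: fetalhand
Title: Inferring Postnatal Handedness from Fetal Arm-Movement Kinematics
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for laterality analysis of fetal arm-movement
    kinematics recorded by 4D ultrasonography at gestational weeks 14, 18 and
    22. Extracts movement time (MT) and time-to-peak-velocity (TPV) from
    calibrated 2-D trajectories, computes per-fetus hand-asymmetry advantages
    (HAA, rHAA), and infers postnatal handedness with robust nonparametric
    statistics: Hodges-Lehmann location estimates, Welch t-tests on ranks,
    Benjamini-Hochberg FDR control, sign-rule classification with permutation
    p-values, silhouette clustering indices, leave-one-out cross-validated
    logistic regression, and binned mutual information with the Panzeri-Treves
    small-sample bias correction. Ships a synthetic cohort generator that
    emulates the statistical structure of such studies so every stage is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
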