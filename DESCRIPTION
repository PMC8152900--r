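Package: neuroplast
Title: Permutation Inference, Centrality Mapping, and Mediation Analysis for
    Longitudinal Exercise Neuroimaging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for longitudinal controlled trials linking
    cardiovascular exercise, brain connectivity, and cognition. Provides
    voxel-wise eigenvector and degree centrality from 4D resting-state
    timeseries via implicit correlation-matrix power iteration, threshold-free
    cluster enhancement (TFCE) with sign-flip permutation inference and
    max-statistic family-wise error correction, a nonparametric-combination
    (Fisher) joint mediation screen with synchronized permutations,
    percentile-bootstrap mediation analysis with heteroscedasticity-consistent
    standard errors and a Huber-type robust variant, robust Johnson-Neyman
    ANCOVA over covariate design points, diffusion-tensor scalar indices, and
    graded-exercise-test fitness indices. A synthetic-cohort generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    RNifti,
    Rcpp,
    sandwich,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
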