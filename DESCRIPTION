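Package: dmriclass
Title: Voxelwise Diffusion MRI Group Classification with Nested
    Leave-One-Out Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies two groups of subjects from voxelwise diffusion MRI
    scalar maps (fractional anisotropy and NODDI-derived metrics). Implements
    the full analysis chain: a synthetic cohort and metric-map generator, a
    small diffusion-tensor forward model with log-linear fitting and
    fractional anisotropy computation, white-matter masking by mean-FA
    thresholding, voxelwise age residualization, mass-univariate t-statistic
    feature screening, from-scratch linear support vector machine solvers
    (least-squares SVM and sequential minimal optimization), nested
    leave-one-out cross-validation with inner AUC-based hyperparameter
    selection, and sensitivity/specificity/AUC reporting with
    misclassification-overlap and subgroup comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
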