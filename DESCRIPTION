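Package: v1facedecode
Title: Simulation and Decoding of Task-Dependent Face Information in
    Retinotopic Subregions of V1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a region-of-interest
    fMRI decoding pipeline for face categorization in primary visual
    cortex.  Generates synthetic rapid event-related BOLD experiments with
    known ground truth (condition- and task-dependent multivoxel patterns,
    phase-encoded rotating-wedge mapping runs, gaze traces), and provides
    the full analysis chain: linear detrending and high-pass filtering,
    double-gamma haemodynamic response modelling, FIR deconvolution and
    single-trial GLM estimation, polar-angle phase mapping by shifted
    cross-correlation, patch-of-interest definition from mapping contrasts
    with FDR thresholding and a dilation-subtraction rule, sub-sampled
    leave-one-run-out linear SVM decoding with train-derived [-1, 1]
    normalization, repeated-measures ANOVA, Holm-Bonferroni correction,
    and saccade screening of eye-tracking traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
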