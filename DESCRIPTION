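Package: paincoding
Title: Model-Based Analysis of Pain Responses Under Probabilistic Cueing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing competing models of pain processing with
    condition-level physiological and neural response amplitudes from
    probabilistic cue-conditioning experiments. Generates counterbalanced
    cue-stimulus designs, encodes stimulus-intensity, additive-expectation
    and predictive-coding response models (with pain, signed and absolute
    prediction-error variants), scores skin conductance and pupil response
    amplitudes from raw traces, and compares models with default
    Zellner-Siow (Cauchy mixture-of-variance) g-prior Bayes factors
    evaluated by deterministic quadrature. Includes a synthetic-data
    generator with recorded ground truth for model- and parameter-recovery
    studies, repeated-measures factorial ANOVA, voxel-wise Bayes-factor
    maps with anterior-posterior gradient profiles, and multivariate
    pattern-expression scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    RNifti
Config/testthat/edition: 3
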