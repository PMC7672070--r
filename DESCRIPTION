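Package: bagpipe
Title: Brain-Age Gap Pipeline: 3D CNN Age Prediction, Regional
    Importance, Phenome Scans and Mendelian Randomisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a
    brain-age-difference analysis pipeline. Predicts "healthy" brain age
    from 3D structural volumes with a small residual 3D convolutional
    network trained by Adam on mean squared error, removes the
    regression-to-the-mean age bias with a training-set linear
    correction, attributes predictions to atlas regions by cross-subject
    permutation importance, scans many phenotypes for association with
    the brain-age difference (linear, logistic and cumulative-logit
    models with Bonferroni and Benjamini-Hochberg control), and probes
    causality with two-sample Mendelian randomisation (inverse-variance
    weighted, MR-Egger, weighted median, Cochran's Q). A synthetic-cohort
    generator plants known age signal, trait links and causal effects so
    every stage is verified by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
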