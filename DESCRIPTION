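Package: fetalgrowth
Title: Normative Fetal Brain Growth Modeling and Cortical Surface Morphometry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing normative fetal brain development from
    anatomical MRI segmentations: sigmoidal growth-curve fitting (linear,
    quadratic, three- and four-parameter logistic, and Gompertz families) with
    BIC model selection and derived growth descriptors; two-stage inference of
    sex and confound effects via random-intercept linear mixed models on
    residuals with Satterthwaite degrees of freedom and Bonferroni correction;
    compartment volumetry from integer label volumes; mid-cortical surface
    extraction with discrete mean curvature, non-dimensionalized curvature,
    and morphometric thickness; and vertex-wise logistic mapping of cortical
    surface-area expansion. Includes synthetic mixed-longitudinal cohort and
    geometric phantom generators with analytic ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    lmerTest,
    Matrix,
    igraph,
    EBImage,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
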