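Package: LungSSM
Title: Statistical Shape Modelling of Lung and Fissure Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building statistical shape models (SSMs) of the human
    lungs and lobar fissures from segmented surface point clouds. Provides
    bicubic Hermite finite-element surface meshes with 12 degrees of freedom
    per node, regularised linear least-squares mesh fitting, generalised
    Procrustes alignment with an optional scale normalisation (size-inclusive
    and size-exclusive models), PCA-based extraction of shape modes with
    standard-deviation-unit subject scores, per-mode association statistics
    against age, sex, BMI and lung volume, and a synthetic cohort generator
    with covariate-linked planted shape effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
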