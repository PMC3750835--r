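Package: corrdiff
Title: Correlated Diffusion Imaging of Multi-b-Value Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes correlated diffusion imaging (CDI) maps from
    multi-b-value diffusion-weighted MRI: the local joint correlation of
    signal attenuation across gradient-pulse configurations, estimated as
    the sub-volume mean of the across-acquisition signal product within a
    diffusion-weighting range. Includes the apparent diffusion coefficient
    (ADC) log-linear baseline, Stejskal-Tanner b-value arithmetic, NIfTI-1
    and FSL .bval input/output, a synthetic prostate phantom generator with
    mono-exponential tissue decay and Rician magnitude noise, and an
    evaluation protocol with binormal ROC analysis, a two-class
    maximum-likelihood voxel classifier, leave-one-out cross-validation and
    Fisher class-separability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
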