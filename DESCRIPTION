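Package: additivesba
Title: Additive Systems of Stand Basal Area Models for Mixed Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits stand basal area (SBA) growth models for two-species
    mixed forests and enforces additivity between species-level and
    stand-level predictions.  Provides the Korf, Schumacher and Richards
    base growth forms and their extensions with site index, stand age at
    breast height and Reineke stand density index as covariates;
    equation-wise nonlinear least squares with multi-start initialisation;
    an adjustment-in-proportion (AP) system that disaggregates a fitted
    stand total into species shares; and nonlinear seemingly unrelated
    regression (NSUR) by iterated feasible generalised least squares with
    an estimated cross-species error covariance.  Includes goodness-of-fit
    metrics, k-fold cross-validation, method-comparison arithmetic, and a
    synthetic plot generator calibrated to published aspen-birch
    mixed-stand summaries for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: minpack.lm, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
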