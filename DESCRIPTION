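Package: strokemismatch
Title: PWI-DWI Mismatch Estimation and Thrombolysis Decision Support for
    Acute Stroke MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated estimation of the perfusion-diffusion (PWI-DWI)
    mismatch in acute ischemic stroke MRI. Computes apparent diffusion
    coefficient (ADC) and time-to-peak (TTP) parameter maps from
    diffusion-weighted image pairs and dynamic susceptibility contrast
    series, performs whole-brain masking and lesion laterality detection,
    delineates the diffusion core and the hypoperfused lesion against a
    mirrored contralateral reference, and applies imaging-based
    thrombolysis eligibility rules (mismatch volume and ratio thresholds)
    together with an AHA-style contraindication screen. Includes
    multi-rater consensus masks, confusion-matrix and volumetric-agreement
    validation statistics, rank-sum group comparisons, a Gini-impurity
    classification tree for decision-factor analysis, and a synthetic
    stroke phantom and cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
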