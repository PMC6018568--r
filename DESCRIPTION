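Package: lesionboot
Title: Bootstrap Reproducibility of Voxel-Based Lesion-Deficit Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how sample size affects the reproducibility of
    voxel-based lesion-deficit mapping. Provides a calibrated synthetic
    cohort generator (behavioural T-scores, lesion sizes, fuzzy and binary
    lesion volumes with a designated effect region), mass-univariate
    voxel-wise regression with permutation-based family-wise error
    correction for region-of-interest discovery, partial-correlation effect
    sizes with flat-prior credible intervals and closed-form power and
    sign-error calculators, and a bootstrap resampling study that
    quantifies effect-size inflation (the winner's curse), wrong-sign
    estimates, and credible-interval coverage across sample sizes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
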