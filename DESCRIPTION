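Package: tractpls
Title: Longitudinal Tract-Wise Diffusion Trajectories and PLS Correlation with Clinical Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage analysis pipeline for longitudinal tract-averaged
    diffusion MRI metrics (FA, AD, RD, MD over 18 white-matter tracts).
    Stage one characterizes developmental trajectories per tract and metric
    with random-intercept mixed models, selects the polynomial age trend
    (constant, linear, quadratic) by BIC, tests group and age-by-group
    interaction effects by likelihood ratio, and adjusts p-values by the
    Benjamini-Hochberg false discovery rate. Stage two relates
    age-residualized, per-subject white-matter deviation scores to
    dichotomized clinical risk factors through partial least squares
    correlation: singular value decomposition of the cross-correlation
    matrix, permutation testing of the singular values, bootstrap stability
    ratios for the saliences, and per-subject latent brain and behavior
    scores. A synthetic-cohort generator with planted ground truth supports
    calibration and recovery testing in the absence of deposited MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
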