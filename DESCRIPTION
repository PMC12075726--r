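Package: ngdwi
Title: Non-Gaussian Diffusion MRI Models for Lymph Node Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of multi-b-value diffusion-weighted
    MRI signal decays under four models (mono-exponential, stretched
    exponential, fractional-order calculus, and continuous-time random walk
    with a Mittag-Leffler kernel), including two-stage Levenberg-Marquardt
    voxel-wise parameter mapping, ROI summarization, a Rician-noise phantom
    and cohort simulator, and the diagnostic statistics used to separate
    benign from metastatic retropharyngeal lymph nodes: group tests, ROC
    analysis with Youden cutoffs, DeLong comparisons of correlated AUCs,
    logistic regression with odds ratios, and intraclass correlation
    coefficients.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pROC,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
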