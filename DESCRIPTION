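Package: gsembrain
Title: Latent General-Intelligence and Brain-Structure Modelling with
    Full-Information Maximum Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structural-equation-modelling toolkit for large
    brain-imaging cohort studies of general cognitive ability. Provides a
    full-information maximum-likelihood (FIML) covariance-structure engine
    that handles block missingness, a confirmatory factor model of the
    latent g factor with modification-index-guided respecification,
    global and regional brain-g association models (bivariate and MIMIC),
    age and sex measurement-invariance and moderation tests,
    Benjamini-Hochberg false-discovery-rate families, and out-of-sample
    prediction of g from weighted regional composites. Includes a
    synthetic cohort generator that emulates the cognitive battery, MRI
    volumetrics, diffusion tract measures, covariate confounding and
    structural block missingness of a large population imaging study, so
    the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
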