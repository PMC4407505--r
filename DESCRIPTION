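Package: scenestats
Title: Low-Level Scene Image Statistics and Esthetic Preference Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ten low-level color and spatial statistics of scene
    images (HSV channel means and dispersions, grayscale histogram entropy,
    weighted dual-threshold Canny edge density, straight-edge density via
    gradient-direction connected components, and the disorganized edge ratio),
    and links them to esthetic preference and perceived naturalness ratings.
    Provides parametric synthetic scene and rating generators, per-image rating
    aggregation with within-subject reaction-time z-scoring, an ordinary
    least-squares decomposition of perceived naturalness into feature-modeled
    and non-modeled components (with color-only and structure-only submodels),
    reaction-time moderation models with simple-slopes summaries, and quadratic
    discriminant classification of preferred versus non-preferred images under
    pairwise leave-one-out cross-validation with backward feature elimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    ggplot2,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
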