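Package: sbimeta
Title: Meta-Analysis of Soybean-Based Intercropping Effects on Soil
    Microbial Communities and Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative synthesis toolkit for paired
    monoculture-versus-intercropping studies of soil microbial community
    traits (Shannon, Chao1, richness, beta-diversity, community
    structure) and crop yield.  Builds log response-ratio (lnRR) effect
    sizes with sampling variances and coefficient-of-variation based
    standard-deviation imputation, converts two-dimensional ordination
    coordinates into one-dimensional beta-diversity and structure
    response ratios, pools effects with a study-nested multilevel
    random-effects model fitted by restricted maximum likelihood, and
    runs subgroup (omnibus Q_M) analyses with single-step post hoc
    comparisons.  Publication-bias diagnostics (Rosenthal fail-safe
    number with the 5n + 10 robustness rule, Begg-type Kendall rank
    test), weighted meta-regression with AIC/BIC model selection and
    quadratic turning-point extraction, Mantel and partial Mantel
    permutation tests, and permutation-based moderator importance from a
    tree ensemble complete the pipeline.  A seeded synthetic
    study-database generator with known truth makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    multcomp,
    jsonlite,
    optparse
Config/testthat/edition: 3
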