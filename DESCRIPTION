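Package: phasemap
Title: Data-Driven Mapping of Behavioural Problem Profiles Across Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping profiles of behavioural problems across
    developmental stages in two-wave questionnaire cohorts. Implements the
    full analysis chain: cleaning of ordinal and visual-analogue ratings
    (missing-item screening, expectation-maximisation imputation, kernel
    density discretisation, univariate and Mahalanobis outlier screening),
    polychoric exploratory factor analysis with varimax rotation, parallel
    analysis and bootstrap factor-stability assessment, hybrid hierarchical
    clustering combining mutual clusters with tree-structured vector
    quantisation, Calinski-Harabasz and silhouette diagnostics,
    Fowlkes-Mallows dendrogram comparison with a permutation null,
    cross-wave transition tables with equal-split chi-squared and
    proportion z-tests, and mixed-design ANOVA utilities with
    Greenhouse-Geisser correction and noncentral-F power analysis.
    A synthetic two-wave cohort generator with planted factor structure,
    cluster prototypes and transition matrix supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    mclust,
    car,
    withr
Config/testthat/edition: 3
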