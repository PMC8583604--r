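Package: twovisit
Title: Two-Visit Longitudinal Cohort Analysis with Random-Intercept Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pre-post (two-visit) chronic-disease monitoring cohorts:
    a from-scratch random-intercept Gaussian mixed model estimated by profile
    (restricted) maximum likelihood with Wald inference, group-comparison
    descriptive tables (median/IQR summaries, Pearson chi-square and
    Kruskal-Wallis tests), Benjamini-Hochberg multiplicity adjustment across
    outcome families, a Monte Carlo power and sample-size engine with a
    closed-form analytic oracle, and a synthetic two-visit cohort generator
    with exact per-variable missingness for reproducing the statistical
    structure of care-pathway effectiveness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
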