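Package: hspmark
Title: Urinary Heat-Shock-Protein Network Screening and Cancer Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for heat-shock-protein (HSP) chaperone
    biomarkers in urine proteomes. Simulates labeled iFOT intensity cohorts
    with sentinel-coded missingness, applies a detection filter, screens
    proteins with a two-stage nonparametric procedure (Kruskal-Wallis
    followed by Dunn's test against healthy controls with Holm-Bonferroni
    correction), builds chaperone-network features (ratios, products and
    family sums over protein levels), trains a gradient-boosted tree cancer
    classifier inside a Bayesian-optimization-driven recursive
    feature-elimination loop, and explains the selected model with exact
    tree Shapley attributions and clipped z-score summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
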