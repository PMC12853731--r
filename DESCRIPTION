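Package: pdpaudit
Title: Interpretability Audits for Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Model-agnostic interpretability audit for tabular clinical risk
    models, built around three pillars: partial-dependence analysis (one- and
    two-dimensional, gated by repeated permutation importance with a
    relative-influence threshold), Monte-Carlo permutation-sampling Shapley
    attribution in log-odds units, and a PDP-SHAP directional-concordance
    validation statistic. Includes a synthetic cohort generator emulating the
    structure of national surgical-registry total-joint-arthroplasty data
    (marginal distributions, sentinel missing codes, "90+" age coding,
    physiologically implausible values, and a logistic outcome model with
    planted main and interaction effects) so that every stage of the audit is
    testable end to end without access to proprietary registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
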