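Package: clasp
Title: Conditional-Logistic Affected-Sib-Pair Linkage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-free linkage analysis of affected sib pairs under the
    conditional-logistic model: identity-by-descent (IBD) posterior
    probabilities from marker data by exact enumeration, maximised LOD
    scores under six constraint regimes (including the possible-triangle
    genetic constraints and the one-parameter minmax model, with or
    without covariates), chi-bar-square mixture null distributions whose
    mixing proportion is derived by the Self-Liang cone geometry, exact
    critical LOD scores and asymptotic p-values, and a gene-dropping
    simulator for empirical null-distribution studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
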