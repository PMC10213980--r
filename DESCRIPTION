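Package: coexmeta
Title: Consensus Co-Expression Networks and Cross-Cohort Persistence of
    Molecular Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-cohort analysis of feature-by-sample abundance data:
    soft-thresholded unsigned correlation networks and topological overlap,
    cross-cohort consensus networks, module detection with eigengene
    summaries, permutation module-preservation Z statistics,
    covariate-adjusted differential abundance with Stouffer and
    random-effects meta-analysis, directional persistence filtering,
    hypergeometric pathway over-representation with sign-based activation
    scores, and cis protein quantitative trait locus mapping.  Includes a
    synthetic multi-cohort data generator with planted modules, case
    effects, trait loadings, and cis genetic effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
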