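Package: villagessl
Title: Village-Level Prevalence Mapping by Bias-Corrected Semisupervised
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of child anthropometric-failure prevalence
    (stunting, underweight, wasting) for census villages from a sparse survey
    of GPS-displaced clusters.  Provides a synthetic-country generator with a
    state/district/village hierarchy, precision-weighted cluster prevalence
    estimation via a four-level random-intercept logistic model fitted by
    MCMC, fuzzy spatial linkage of displaced survey clusters to village
    polygons, graph-harmonic semisupervised regression over a village-feature
    proximity graph, an iterative bias-correction scheme for fuzzy
    cluster-to-village labels, variance partitioning across geographic
    levels, and the accompanying descriptive and sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    glmmTMB,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
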