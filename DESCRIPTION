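Package: benthonet
Title: Bioassessment Metrics and Null-Model Co-Occurrence Networks for
    Stream Macroinvertebrate Communities
Version: 0.1.0
Authors@R: person("benthonet", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline relating oil-and-gas development to stream
    benthic macroinvertebrate (BMI) communities. Provides a synthetic-data
    generator with planted stress effects and block co-occurrence structure,
    well-to-catchment attribution and density computation, taxonomic and
    functional bioassessment metrics with a surrogate index of biotic
    integrity, permutation-null co-occurrence network inference with
    standardized effect sizes and Benjamini-Hochberg edge filtering,
    stratified subsampling network ensembles, and random-intercept linear
    mixed models with standardized effect reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
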