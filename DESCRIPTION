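Package: occbias
Title: Bias Assessment for Academic and Citizen-Science Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify taxonomic, spatial, temporal and
    environmental sampling biases in Darwin-Core-style biodiversity
    occurrence records, stratified by data source (academic versus
    citizen science). Implements source classification from
    basisOfRecord and dataset metadata, a two-tier record cleaning
    workflow, per-order composition and user-preference summaries, a
    range-size/record-count proportionality index, a nearest-neighbour
    clustering index with a uniform random null, a Bayesian Poisson
    distance-decay model of sampling effort versus accessibility
    features, additive weekly/holiday decomposition of daily record
    counts, and PCA-based environmental-space coverage. A fully seeded
    synthetic occurrence generator with known, controllable biases
    supports parameter-recovery testing of every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    rjags,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
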