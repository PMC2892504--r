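Package: delaynet
Title: Time-Delay Linear Regression Networks from Short Time-Course
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs directed, signed, delay-annotated gene regulatory
    networks from short time-course expression data. Each target gene is
    modelled as a linear combination of candidate regulators acting with
    individual time delays; regulators are screened by their best
    single-regulator adjusted R-squared, then forward-selected together
    with their delays under the Akaike information criterion. Includes
    baseline log-ratio preprocessing, replicate merging on a shared
    lifeline, cubic-spline expansion to a uniform time grid, network
    export to TSV and GraphML, consistency scoring against curated
    reference edge sets, and a seeded synthetic benchmark generator with
    known regulatory truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
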