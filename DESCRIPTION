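Package: taxolit
Title: Taxonomic Bias in Ecological Literature via Text Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines bibliographic records (title, author keywords, abstract)
    for scientific names by matching one- and two-word sequences against a
    taxonomy registry with synonym resolution, filters records into marine
    ecosystems by exact phrase queries, aggregates matches into taxon-by-
    ecosystem occurrence matrices, and quantifies taxonomic bias in research
    effort with Shannon evenness, Chao1 richness, average taxonomic
    distinctness (delta+) with randomization funnels, individual-based
    rarefaction, and effort-versus-richness residual rankings from a
    spline model with phylum-level random intercepts. Includes a seeded
    synthetic-data generator (registry + corpus + plant log) so every
    pipeline stage is testable against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    knitr
Config/testthat/edition: 3
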