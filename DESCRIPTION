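Package: dietweb
Title: Weighted Directed Food Webs from Predator Diet Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds cumulative, sector-specific weighted directed food webs
    from tabular predator-diet observation records (fraction of occurrence
    and fraction of diet by weight metrics). Provides dataset refinement
    (season, region and taxon-quality filters), longitude-based ocean sector
    assignment with dateline wraparound, taxon-to-trophic-group aggregation
    at fine and coarse resolution, network structure statistics (connectance,
    link density, weighted out-degree strength of mid-trophic groups),
    source-randomized species-accumulation curves with an exact
    hypergeometric expectation and negative-exponential fits, and a
    stomach-level synthetic diet-record simulator for testing every pipeline
    stage without external data.
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
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
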