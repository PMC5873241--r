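Package: dietspec
Title: Individual Diet Specialization in Provisioning Predators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies individual foraging specialization from prey records
    recovered from provisioned nests (e.g. mud-dauber wasp nest cells).
    Computes per-individual proportional-similarity indices (PSi) and the
    population index IS with a multinomial Monte Carlo null, the diet-overlap
    network clustering index Cws, the nestedness index NODF with a
    marginal-probability null model, and the WIC/TNW decomposition of niche
    width on continuous prey traits with a permutation null. Includes a
    synthetic-population generator with controllable specialization,
    nestedness, modularity, temporal drift and prey-size structure, plus a
    pipeline reproducing single-bout, pooled-bout, temporal-consistency and
    single-resource-subset analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
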