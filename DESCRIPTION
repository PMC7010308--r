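Package: rearnet
Title: Spatio-Temporal Analysis of Saproxylic Rearing Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing host tree x wood-boring beetle interaction
    networks assembled from rearing experiments, in which branch sections are
    exposed under contrasting spatio-temporal treatments and emerging adults
    are attributed to their host wood. Provides Hill-number diversity profiles
    with bootstrap confidence intervals and sample coverage, Baselga
    partitioning of compositional dissimilarity, Poisot-style interaction
    dissimilarity (rewiring versus species turnover), weighted network
    structure (WNODF nestedness, Barber bipartite modularity via label
    propagation, H2' specialization, Horn niche overlap), species-level
    indices (d', effective partners, species strength), Patefield
    fixed-marginal null models with p-values and z-scores, wood and body-size
    trait formulas, correlation-matrix PCA of traits against network roles,
    and a seeded synthetic rearing-experiment generator so the full pipeline
    runs without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
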