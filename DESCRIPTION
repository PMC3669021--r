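Package: phenotier
Title: Four-Tiered Graphs for Binary Phenotype Profiles of Bacterial Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for explaining phenotypic clustering of cultured bacterial
    isolates characterized by binary phenotype profiles (e.g. API ZYM enzyme
    activities or Biolog PM carbon-source utilization). Strains and resources
    are reduced to equivalence classes of identical profiles, strain classes
    are ordered by a principal component analysis of their normalized
    Hamming-similarity matrix, and the result is laid out as a four-tiered
    strains -> strain classes -> resource classes -> resources graph with
    overlap separation and barycenter placement, exported as GraphML.
    Includes optical-density binarization, profile summary statistics,
    Pearson/Mantel correlation of distance matrices, Wilcoxon group
    comparisons, and a synthetic-data generator with planted class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
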