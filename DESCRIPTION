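Package: peatnet
Title: Co-Occurrence Networks and Keystone Taxa for Peatland Soil Carbon Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying keystone bacterial taxa
    that regulate soil carbon mineralization in peatlands. Reads, filters and
    rarefies OTU count tables; estimates compositionally robust taxon-taxon
    correlations with SparCC and permutation-based significance; builds
    thresholded co-occurrence networks; detects modules and classifies node
    roles with within-module degree (Zi) and participation coefficient (Pi);
    computes module eigengenes, module-trait correlations, per-taxon gene
    significance (GS) and module membership (MM), and screens hub genes and
    keystone taxa. Also provides soil carbon chemistry calculations (CO2
    incubation mineralization rate, FTIR 1630/1030 recalcitrance index, DOC
    carbohydrate calibration) and a seeded synthetic-data generator that
    emulates a paired natural/cultivated peatland sampling design with
    planted correlation modules and trait-module associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
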