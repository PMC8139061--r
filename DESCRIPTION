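Package: sewerstates
Title: Seasonal Community States and Human-Source Partitioning in Sewer Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing monthly 16S rRNA amplicon sequence variant (ASV)
    time series from wastewater conveyance systems. Partitions ASVs into
    human-associated and resident-sewer fractions by exact-identity matching
    against a human-microbiome reference with a percentile-threshold
    reclassification rule, and characterises seasonal community steady states
    with Bray-Curtis dissimilarity, principal coordinate analysis, PERMANOVA,
    environmental vector fitting, indicator-species analysis over consecutive
    three-month windows, and gap-aware autocorrelation. Includes a seeded
    synthetic-data generator with ground-truth labels so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
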