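Package: rarecycle
Title: Rare and Abundant Soil Microbial Taxa, Co-Occurrence Networks and
    Multi-Nutrient Cycling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline linking the diversity of rare and abundant
    soil microbial taxa to a soil multi-nutrient cycling index (MNC) across
    crop types.  Provides OTU-table and nutrient-table input/output,
    rare/abundant taxa partitioning by relative-abundance thresholds, alpha
    and beta diversity with ordination and permutation statistics
    (PERMANOVA, Mantel, Kruskal-Wallis, Duncan's multiple range test),
    min-max normalised multi-nutrient cycling indices, Spearman-thresholded
    co-occurrence networks with topology and robustness summaries, a
    recursive path model with chi-square/df and RMSEA fit indices,
    random-forest permutation importance, a seeded synthetic-data generator
    emulating the study design, and a one-call pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    biomformat,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
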