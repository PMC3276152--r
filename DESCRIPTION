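Package: fragileMap
Title: Genome-Wide Mapping of Replication-Stress Chromosome Fragility from
    Two-Channel Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds smoothed single-stranded DNA and double-strand-break
    ratio profiles from two-channel genomic microarray measurements, calls
    significant breakage sites against the genome-wide median, correlates
    profiles, and tests the association between break sites and categorized
    replication origins (or other point features) with a midpoint-distance
    randomization test. Includes a synthetic two-channel array simulator
    with planted enrichment peaks so the whole pipeline, including the null
    calibration of the randomization test, can be exercised without
    hybridization data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
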