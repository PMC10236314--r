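Package: cnvcoex
Title: CNV-Conditioned Gene Co-Expression Network Layers
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds copy-number-conditioned gene co-expression networks from
    expression and copy-number matrices using plug-in conditional mutual
    information (CMI) over discretized data, one network layer per
    conditioning gene. Layers are compared all-against-all with the
    two-sample Kolmogorov-Smirnov statistic, and edges are classified by
    chromosomal geography (intra-cytoband, inter-cytoband, inter-arm) with
    cumulative growth curves, degree profiles and cytoband hotspot
    summaries. Includes a block-covariance synthetic data generator with a
    tunable CNV-to-co-expression coupling so the whole pipeline can be
    exercised and validated without access to controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
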