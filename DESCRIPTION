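Package: ffedomics
Title: Fractional Factorial Experimental Design for Multiplexed Omics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs two-level orthogonal-array (L8) fractional factorial
    exposure designs with exact alias algebra, and couples them to a layered
    omics analysis: negative-binomial GLM differential expression across
    global, clinical-background, cell-line and interaction contrasts;
    preranked gene-set enrichment with a permutation null and
    enrichment-map-style similarity networks; permutation enrichment of gene
    groups across brain regions and developmental periods; a simplified
    differential exon usage test on flattened exon bins; and
    internal-standard one-point calibration of metabolite features. Seeded
    generators simulate every input with known ground truth so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
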