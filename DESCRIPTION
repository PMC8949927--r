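Package: qtlcascade
Title: QTL Interval Mapping and Candidate-Gene Prioritization for Mouse Backcrosses
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing candidate genes under a quantitative trait
    locus (QTL) in a two-strain mouse backcross. Implements single-QTL interval
    mapping by an EM normal-mixture scan with permutation-based genome-wide
    significance thresholds, strain-vs-strain haplotype mapping by windowed
    SNP-density filtering, differential-expression filtering across bulk islet
    contrasts, qPCR relative quantification, and single-cell cluster expression
    profiling, together with seeded synthetic-data generators that emulate an
    (NZOxB6)N2 cross and its downstream candidate cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
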