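Package: longevol
Title: Longitudinal Tumor Evolution Analysis from Serial Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of longitudinal (serial) tumor exome sequencing:
    cancer-cell-fraction (clonality) estimation from variant allele
    frequencies, tumor purity and local copy number; multi-timepoint
    Gaussian mixture clustering of mutations with BIC model selection and
    classification of clone trajectories (preserved, lost, emerged);
    6-class and 96-class trinucleotide substitution spectra, hypermutation
    flagging and mismatch-repair gene screening; chromothripsis detection
    from copy-number oscillation and clustered high-support breakpoints
    with double-minute candidate extraction from the breakpoint graph;
    plus a synthetic-data generator that emits VCF/SEG/BEDPE fixtures with
    truth tables for every simulated quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
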