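Package: pvcomp
Title: Comparison of Multi-Method p-Value Tables from Omics Analyses
Version: 0.1.0
Authors@R: person("Analysis", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares significance results produced by several statistical
    methods applied to the same set of genetic markers (genes, probes, SNPs,
    or collapsed rare-variant regions). Reads a markers-by-methods table of
    p-values from TSV, computes all-pairs correlation views on the -log10
    scale, partitions markers into Venn classes for any two methods at
    user-chosen thresholds, sweeps significance cut-offs, builds a
    color-coded multi-method significance table with commonly-significant
    marker extraction and Fisher's combined p-values, constructs annotation
    links (dbSNP, NCBI Gene, DAVID), and renders static TSV/HTML/image
    reports. Includes synthetic p-value and two-group expression simulators
    so every component is testable without external data, plus a scriptable
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
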