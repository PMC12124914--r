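Package: cfdecon
Title: Fragment-Level Cell-Free DNA Methylation Deconvolution
Version: 0.1.0
Authors@R:
    person("cfdecon", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for tracing the tissue of origin of plasma cell-free DNA
    (cfDNA) from bisulfite sequencing data. Builds fragment-level joint
    methylation states from Bismark-style read intervals and per-CpG
    methylation calls, summarizes reference methylation markers as per-class
    Beta distributions, estimates tumor burden with a two-class
    fragment-likelihood mixture, and quantifies multi-tissue cfDNA
    composition with an explicit unknown-tissue class. Includes a
    ground-truthed synthetic-data generator emulating the Bismark file
    dialects and a command-line entry point covering the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
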