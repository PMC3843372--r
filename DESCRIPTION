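Package: tagctools
Title: Taxon-Annotated GC-Coverage Plots for Contamination Screening of
    Draft Assemblies
Version: 0.1.0
Authors@R:
    person("TAGC", "Maintainers", email = "tagctools@example.org",
           role = c("aut", "cre"))
Description: Collates per-contig GC content, per-library read coverage and
    best-hit taxonomy from a preliminary genome assembly into a single
    tab-separated table, renders taxon-annotated GC-coverage ("blob")
    plots, and bins contigs and their reads (with mate rescue) to separate
    a target genome from contaminants and symbionts in mixed-organism
    sequencing data.  Includes a seeded simulator that produces complete
    synthetic input bundles (assembly, alignments, hits, taxonomy dump,
    paired reads) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    ggplot2,
    jsonlite,
    grDevices,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
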