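Package: ggrs
Title: Genotyping by Genome Reducing and Sequencing: Library Design, Simulation and SNP Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for GGRS (genotyping by genome reducing and
    sequencing), a restriction-enzyme based reduced-representation genotyping
    protocol. Provides in silico restriction digestion of a reference genome
    with IUPAC-degenerate motifs and fragment size selection, multiplex
    capacity and cost planning, constrained variable-length barcode design,
    a paired-end read simulator with per-read truth tables, barcode
    demultiplexing with the four GGRS read-quality filters, SNP retention
    filtering (call quality, call rate, mean depth, minor allele frequency)
    on multi-sample VCFs, and per-chromosome marker density, block occupancy
    and platform comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
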