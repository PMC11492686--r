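Package: mitorecomb
Title: Repeat-Mediated Recombination and Structural Analysis of Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Mitorecomb", "Developers", email = "mitorecomb@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the dynamic structure of plant mitochondrial
    genomes from long reads and assembly graphs. Quantifies repeat-mediated
    homologous recombination by counting long reads that span a repeat copy
    with a minimum amount of unique flanking sequence on both sides, resolves
    an assembly graph into representative linear or circular molecules under a
    chosen conformation per repeat pair, detects simple sequence repeats and
    dispersed repeats (forward, palindromic, reverse, complement), computes
    relative synonymous codon usage (RSCU) for protein-coding gene sets, and
    identifies mitochondrial plastid DNA segments (MTPTs) by seeded local
    alignment with Karlin-Altschul E-values. Includes a seeded synthetic-data
    generator (toy multi-contig genomes with two-copy repeats, conformational
    isoform mixtures, long reads with configurable error, planted plastid
    transfers, and CDS sets with controlled codon bias) used by the test
    suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
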