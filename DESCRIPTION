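Package: mitosplit
Title: Characterization of Multipartite Mitochondrial Genomes and Putative
    Extrachromosomal microDNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize circular mitochondrial chromosomes from
    annotation tables and sequence: coordinate arithmetic on circular
    genomes, base composition and AT/GC strand skews, translation under the
    mold/protozoan/coelenterate mitochondrial code, codon usage, intergenic
    region (IGR) size taxonomy, imperfect terminal direct/inverted repeat and
    tandem-motif detection with regression of repeat counts on IGR length,
    gene-order comparison between circular genomes, and an evidence chain
    (junction-spanning reads, flank diversity, read depth, NUMT
    discrimination) for calling small extrachromosomal circular DNAs
    (microDNAs). Includes a seeded synthetic-data generator producing
    ground-truthed circular chromosomes, planted repeats, microDNA circles,
    tandem-array decoys, NUMT copies and paired-end reads, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
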