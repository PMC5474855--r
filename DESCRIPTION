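Package: polyorigin
Title: Ancestral-Origin Classification and Assembly Integration for Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for partitioning an allopolyploid genome assembly by ancestral
    (subgenome) origin from parental read coverage: per-base and per-scaffold origin
    classification, rule-based gene origin assignment with polymorphism-based rescue
    of collapsed genes, expressed-gene filtering from TPM tables, merging of local
    (whole-genome-profiling) contigs into a shotgun assembly from BLAST high-scoring
    pairs, VCF-driven consensus correction, and pseudomolecule construction with AGP
    output. Includes a seeded simulator of an allotetraploid genome with known
    per-base origin so the whole pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
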