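Package: xenacomp
Title: Comparative Genomics of Acoelomorph Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale comparative analysis of draft animal
    genomes, built around the questions raised by the first nemertodermatid
    genome: assembly contiguity and composition summaries (N50, N content,
    soft-masked repeat fraction), gene-model architecture statistics from
    GFF3 annotations (genes per contig, exons per gene, intron lengths),
    taxon-based contig decontamination from tabular alignment hits
    (best-sum bitscore assignment and lineage keep policies), orthogroup
    clade-partition analysis of gene content (exclusive, metazoan-shared and
    bilaterian-shared sets), and a statistical comparison of gene
    architecture across clades using a Shapiro-Wilk/Bartlett gated
    ANOVA-or-Kruskal-Wallis cascade with Bonferroni or Dunn post-hoc tests.
    A fully seeded synthetic-data generator produces manifest-backed
    FASTA/GFF3/TSV fixtures so that every stage of the pipeline can be
    validated against known ground truth without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
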