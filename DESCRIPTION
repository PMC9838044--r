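Package: HDZipKit
Title: Characterization of Plant HD-Zip Gene Families from Transcriptome
    Evidence
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for characterizing a plant
    transcription-factor gene family (HD-Zip) from transcriptome-scale
    evidence. Identifies family members from Pfam-style domain hits and
    classifies the four HD-Zip subfamilies by their diagnostic domain
    combinations; merges multi-method candidate sets with provenance;
    assigns transcripts to genome loci from tabular alignments and detects
    genotype-specific loci; estimates Ka and Ks by the Nei-Gojobori (1986)
    counting method with Jukes-Cantor correction and dates duplications
    with a synonymous molecular clock; analyses expression breadth across
    sample designs against bootstrap random-background controls; builds
    Spearman co-expression networks over a significance-threshold sweep,
    tests network-formation tendency against random gene sets, and calls
    hub genes by connectivity; and quantifies qPCR stress responses by the
    2^-ddCt method. A seeded synthetic-data generator emulates every input
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, Network, Transcriptomics, FunctionalGenomics
RoxygenNote: 7.3.3
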