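Package: gstfam
Title: Two-Species Gene-Family Survey Toolkit (Catalog, Duplication,
    Gain/Loss, Expression, Promoter Analysis)
Version: 0.1.0
Authors@R:
    person("gstfam", "developers", email = "gstfam@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide surveys of a gene family across two
    related plant species, modelled on the glutathione S-transferase (GST)
    family in pepper and tomato. Builds and summarises a family catalog
    with physicochemical annotation (molecular weight, isoelectric point),
    classifies duplicate gene pairs as tandem or segmental with a genomic
    window rule, estimates dN/dS by Nei-Gojobori counting with Jukes-Cantor
    correction and dates duplications from synonymous divergence, labels
    gene-tree nodes by species overlap and tallies most-recent-common-
    ancestor gene units with per-lineage gains and losses, tiers and
    clusters expression matrices (Manhattan distance, average linkage),
    scans promoters for IUPAC cis-element consensi, converts CDNB assay
    kinetics to specific activity, and simulates two-species families by a
    post-split birth-death process with planted ground truth for end-to-end
    testing. Ships a transcription of the published pepper GST catalog as a
    plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
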