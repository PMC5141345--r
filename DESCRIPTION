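Package: argsr
Title: Detection and Functional Reconstruction of Androgen Receptor
    Genomic Structural Rearrangements from Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis pipeline for genomic structural
    rearrangements (GSRs) of the androgen receptor (AR) locus in
    prostate cancer. Merges structural-variant call sets from two
    callers into consensus break fusion junctions, applies support and
    gene-body filters and a cDNA-contamination rule, estimates locus
    copy number against capture-panel control regions and sub-clonal
    variant allele fractions, calls hotspot missense SNVs by dual
    rule-set consensus, reconstructs derivative chromosomes with
    bidirectional coordinate liftover, counts RNA-seq splice junctions
    between exon/intron bins of the derivative architecture, assembles
    and translates rearrangement-dependent truncated receptor (AR-V)
    transcripts, and provides the exact statistics used for cohort
    comparisons. A seeded synthetic-cohort generator supplies
    truth-annotated reference sequences, alignments and call sets so
    the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
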