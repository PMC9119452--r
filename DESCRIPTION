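Package: barcodegap
Title: DNA Barcode Survey Analysis with Kimura-2-Parameter Distances and
    Neighbor-Joining Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for cytochrome oxidase I (COI) DNA barcode
    surveys of the kind used to audit regional fish faunas: collapsing
    aligned barcode sequences into named haplotypes with frequency tables,
    Kimura 2-parameter (K2P) pairwise distances with pairwise deletion and
    saturation flagging, within- and between-species distance summaries and
    barcoding-gap assessment, neighbor-joining tree construction with
    column-resampling bootstrap support, reference-library molecular species
    identification with discrepancy and hybrid-introgression flagging, and
    geography-structured population distance tables.  A seeded synthetic
    survey generator with full ground truth makes every stage testable
    without any sequence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
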