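Package: cosbr
Title: Conditional Knockout Targeting Vector Design by Co-Selection BAC
    Recombineering, In Silico
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for designing conditional knockout (CKO)
    gene targeting vectors built by co-selection BAC recombineering
    (CoSBR). Designs the three synthesis components (FRT-neo-FRT-loxP
    cassette insert, 200-nt loxP oligo with lagging-strand selection,
    gap-repair retrieval insert) plus screening primers; simulates every
    DNA transaction in silico (double- and single-stranded recombineering,
    gap repair, Cre/Flp site-specific recombination, restriction digestion,
    PCR) to verify the final vector base-for-base; and models the
    polyclonal 96-well screening statistics with a Poisson founder model.
    Includes a deterministic synthetic-locus and mock-BAC generator so the
    whole workflow is testable without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
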