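# Built-in sequence constants and the restriction-enzyme table.
#
# The published CKO cassette architecture states only the *lengths* of the
# recombination sites (34 bp each) and of the Pgk1/BGHpA homology segments
# (71 and 60 bp); it does not print sequences. The loxP and minimal FRT
# sequences below are the canonical literature sequences; the Pgk1/BGHpA
# homology segments are fixed synthetic stand-ins (any fixed sequence works:
# the simulator only requires that the cassette insert and the neo fragment
# share them exactly). All constants are overridable via design_parameters().

#' Canonical recombination-site sequences
#'
#' 34-nt loxP (Cre) and minimal 34-nt FRT (Flp) recognition sequences. The
#' toolkit validates that any loxP/FRT feature is exactly 34 bases long.
#'
#' @format Character scalars of 34 bases.
#' @name site_constants
NULL

#' @rdname site_constants
#' @export
LOXP_SEQ <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"

#' @rdname site_constants
#' @export
FRT_SEQ <- "GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC"

# Synthetic stand-in for the 71-bp homology to the 5' end of the mouse Pgk1
# promoter. Marked synthetic: shared verbatim between the designed cassette
# insert and the mock PL452-derived neo fragment, which is all the in-silico
# recombineering step needs.
#' @rdname site_constants
#' @export
PGK1_5P_HOMOLOGY <- "AGGAAGACACCAAGCGCTGTCTGTCCGTCTGTGGAAAGCGGCGCGTAAGAGCCGCCGGCGGCCATGCACAA"

# Synthetic stand-in for the 60-bp homology to the 3' end of the bovine
# growth hormone polyA sequence (see PGK1_5P_HOMOLOGY note).
#' @rdname site_constants
#' @export
BGHPA_3P_HOMOLOGY <- "TCGGTGAAGAGCGTATTCACTGTAGTCGTACAACACATTAAGGGTCCGTTGACAAGGCGA"

#' Built-in restriction enzyme recognition table
#'
#' Recognition sequences for the enzymes the workflow touches. All six are
#' palindromic, so a single-strand scan finds every site. Cut position is
#' taken as the 5' end of the recognition site (band-size resolution makes
#' overhang geometry irrelevant).
#'
#' @return Named character vector of recognition sequences.
#' @export
#' @examples
#' restriction_enzymes()[["BamHI"]]
restriction_enzymes <- function() {
  c(
    BamHI = "GGATCC",
    EcoRI = "GAATTC",
    NotI  = "GCGGCCGC",
    XhoI  = "CTCGAG",
    SpeI  = "ACTAGT",
    BglII = "AGATCT"
  )
}

enzyme_site <- function(enzyme) {
  tab <- restriction_enzymes()
  if (!enzyme %in% names(tab)) {
    stop("unknown restriction enzyme: ", enzyme, call. = FALSE)
  }
  tab[[enzyme]]
}

FEATURE_KINDS <- c(
  "loxP", "FRT", "exon", "CDS", "homology_arm", "marker",
  "restriction_site", "primer_site", "origin", "promoter_end"
)
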