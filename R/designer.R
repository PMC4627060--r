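# Designer: emits the three synthesis components and the screening primer
# pair with the published architectures.
#
#   cassette insert : site5 + 100-nt 5' mini arm + FRT + 71-nt Pgk1-5'
#                     homology + 60-nt BGHpA-3' homology + FRT + 18-nt
#                     spacer + loxP + 100-nt 3' mini arm + site3
#   loxP oligo      : 83-nt flank + 34-nt loxP + 83-nt flank (200 nt), with
#                     2+2 terminal phosphorothioate bonds (annotation only)
#   retrieval insert: NotI + 200-nt 5' arm + XhoI + 200-nt 3' arm
#
# Every homology segment is copied verbatim from the locus (genome-forward
# strand), so each is an exact substring of the locus by construction.

DEFAULT_SPACER <- "GGAACTTCGGAATAGGAA"

#' Design parameters
#'
#' Tunable lengths and enzymes for the synthesis components. Defaults are
#' the published architecture; \code{site_len} is fixed at 34 (loxP/FRT).
#'
#' @param mini_arm_len Mini homology arm length for the cassette (bases).
#' @param oligo_flank_len Oligo flank homology length (bases).
#' @param site_len Recombination-site length; must be 34.
#' @param pgk1_homology_len,bghpa_homology_len Lengths of the Pgk1-5' and
#'   BGHpA-3' homology segments carried by the synthesized insert.
#' @param spacer_len Spacer between the 3' FRT and the cassette loxP.
#' @param retrieval_arm_len Retrieval (gap repair) arm length.
#' @param phosphorothioate_per_end Protected bonds at each oligo terminus.
#' @param cassette_site_enzyme_5,cassette_site_enzyme_3 Release enzymes
#'   flanking the cassette insert (may be identical or different).
#' @param retrieval_linearization_enzyme Enzyme between the retrieval arms.
#' @param retrieval_release_enzyme Enzyme for linearizing the final vector.
#' @param es_arm_range Acceptable ES-cell homology arm length range (bases).
#' @param loxp_seq,frt_seq,pgk1_seq,bghpa_seq,spacer_seq Sequence overrides.
#' @param min_arm Minimum homology length for simulated recombineering.
#' @return A list of class \code{design_parameters}.
#' @export
design_parameters <- function(mini_arm_len = 100L, oligo_flank_len = 83L,
                              site_len = 34L, pgk1_homology_len = 71L,
                              bghpa_homology_len = 60L, spacer_len = 18L,
                              retrieval_arm_len = 200L,
                              phosphorothioate_per_end = 2L,
                              cassette_site_enzyme_5 = "BamHI",
                              cassette_site_enzyme_3 = "BamHI",
                              retrieval_linearization_enzyme = "XhoI",
                              retrieval_release_enzyme = "NotI",
                              es_arm_range = c(2500L, 3500L),
                              loxp_seq = LOXP_SEQ, frt_seq = FRT_SEQ,
                              pgk1_seq = NULL, bghpa_seq = NULL,
                              spacer_seq = NULL, min_arm = 50L) {
  if (site_len != 34L) stop("site_len is fixed at 34 bases", call. = FALSE)
  if (nchar(loxp_seq) != 34L || nchar(frt_seq) != 34L) {
    stop("loxP and FRT sequences must be 34 bases", call. = FALSE)
  }
  if (is.null(pgk1_seq)) pgk1_seq <- substr(PGK1_5P_HOMOLOGY, 1L, pgk1_homology_len)
  if (is.null(bghpa_seq)) bghpa_seq <- substr(BGHPA_3P_HOMOLOGY, 1L, bghpa_homology_len)
  if (is.null(spacer_seq)) {
    spacer_seq <- substr(strrep(DEFAULT_SPACER,
                                ceiling(spacer_len / nchar(DEFAULT_SPACER))),
                         1L, spacer_len)
  }
  p <- list(mini_arm_len = as.integer(mini_arm_len),
            oligo_flank_len = as.integer(oligo_flank_len),
            site_len = 34L,
            pgk1_homology_len = as.integer(pgk1_homology_len),
            bghpa_homology_len = as.integer(bghpa_homology_len),
            spacer_len = as.integer(spacer_len),
            retrieval_arm_len = as.integer(retrieval_arm_len),
            phosphorothioate_per_end = as.integer(phosphorothioate_per_end),
            cassette_site_enzyme_5 = cassette_site_enzyme_5,
            cassette_site_enzyme_3 = cassette_site_enzyme_3,
            retrieval_linearization_enzyme = retrieval_linearization_enzyme,
            retrieval_release_enzyme = retrieval_release_enzyme,
            es_arm_range = as.integer(es_arm_range),
            loxp_seq = loxp_seq, frt_seq = frt_seq, pgk1_seq = pgk1_seq,
            bghpa_seq = bghpa_seq, spacer_seq = spacer_seq,
            min_arm = as.integer(min_arm))
  lens <- unlist(p[c("mini_arm_len", "oligo_flank_len", "pgk1_homology_len",
                     "bghpa_homology_len", "spacer_len", "retrieval_arm_len")])
  if (any(lens <= 0L)) stop("all design lengths must be positive", call. = FALSE)
  class(p) <- "design_parameters"
  p
}

# Copy a homology segment [start, end) verbatim from the locus; reject
# out-of-range segments and any segment containing N (arms must be
# exact-matchable).
locus_segment <- function(locus, start, end, what) {
  if (start < 0L || end > mol_len(locus)) {
    stop(what, " would run off the locus (requested [", start, ",", end, "))",
         call. = FALSE)
  }
  s <- substr(locus$seq, start + 1L, end)
  if (grepl("N", s, fixed = TRUE)) {
    stop(what, " contains N bases; homology segments must be N-free",
         call. = FALSE)
  }
  s
}

#' Design the synthesized cassette insert
#'
#' @param locus Locus \code{dna_molecule}.
#' @param insertion_point 0-based coordinate of the cassette insertion
#'   site (pure insertion between \code{insertion_point - 1} and
#'   \code{insertion_point}), on the genome-forward axis.
#' @param params \code{\link{design_parameters}}.
#' @param strand Gene strand; components are designed in gene orientation,
#'   so for a \code{"-"} strand gene the emitted molecule reads 5'->3' on
#'   the genomic minus strand. This keeps the FRT-neo-FRT-spacer-loxP
#'   order (and hence the post-Flp FRT position inside the floxed
#'   segment) correct relative to the gene.
#' @return Linear \code{dna_molecule} with every segment annotated. With
#'   defaults and 6-bp sites the total length is 463 bases.
#' @export
design_cassette_insert <- function(locus, insertion_point,
                                   params = design_parameters(),
                                   strand = "+") {
  ip <- as.integer(insertion_point)
  if (strand == "-") {
    flipped <- design_cassette_insert(reverse_complement(locus),
                                      mol_len(locus) - ip, params, "+")
    attr(flipped, "insertion_point") <- ip
    attr(flipped, "designed_on") <- "-"
    return(flipped)
  }
  m <- params$mini_arm_len
  arm5 <- locus_segment(locus, ip - m, ip, "5' mini arm")
  arm3 <- locus_segment(locus, ip, ip + m, "3' mini arm")
  site5 <- enzyme_site(params$cassette_site_enzyme_5)
  site3 <- enzyme_site(params$cassette_site_enzyme_3)
  segs <- list(
    list(site5, "restriction_site", params$cassette_site_enzyme_5),
    list(arm5, "homology_arm", "mini_arm_5p"),
    list(params$frt_seq, "FRT", "FRT"),
    list(params$pgk1_seq, "marker", "Pgk1_5p_homology"),
    list(params$bghpa_seq, "marker", "BGHpA_3p_homology"),
    list(params$frt_seq, "FRT", "FRT"),
    list(params$spacer_seq, "marker", "spacer"),
    list(params$loxp_seq, "loxP", "loxP"),
    list(arm3, "homology_arm", "mini_arm_3p"),
    list(site3, "restriction_site", params$cassette_site_enzyme_3)
  )
  mol <- assemble_segments(paste0(locus$id, "_cassette_insert"), segs)
  # The release digest must cut only at the two flanking sites.
  for (enz in unique(c(params$cassette_site_enzyme_5,
                       params$cassette_site_enzyme_3))) {
    pat <- enzyme_site(enz)
    hits <- find_pattern(mol, pat)
    allowed <- c(0L, mol_len(mol) - nchar(site3))
    extra <- setdiff(hits, allowed)
    if (length(extra)) {
      stop(enz, " site inside cassette segment at position(s) ",
           paste(extra + 1L, collapse = ", "),
           " would fragment the cassette on release", call. = FALSE)
    }
  }
  attr(mol, "insertion_point") <- ip
  attr(mol, "designed_on") <- "+"
  mol
}

assemble_segments <- function(id, segs) {
  seqs <- vapply(segs, `[[`, character(1), 1L)
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens
  feats <- feature_table(vapply(segs, `[[`, character(1), 2L), starts, ends,
                         rep("+", length(segs)),
                         vapply(segs, `[[`, character(1), 3L))
  dna_molecule(id, paste(seqs, collapse = ""), "linear", feats)
}

#' Design the 200-nt loxP co-targeting oligo
#'
#' Two flank homologies copied from the locus around the insertion point,
#' with the loxP site between them; on the genome-forward strand. The
#' phosphorothioate bonds (nuclease protection; annotation only) are
#' recorded as 1-based internucleotide bond indices in the
#' \code{phosphorothioate_bonds} attribute.
#'
#' @inheritParams design_cassette_insert
#' @return Linear \code{dna_molecule}; with defaults, 200 nt with the loxP
#'   feature at [83, 117) and bonds \{1, 2, 198, 199\}. When
#'   \code{strand = "-"} the oligo is designed on the gene's coding strand
#'   (the genomic minus strand).
#' @export
design_lox_oligo <- function(locus, insertion_point,
                             params = design_parameters(), strand = "+") {
  ip <- as.integer(insertion_point)
  if (strand == "-") {
    flipped <- design_lox_oligo(reverse_complement(locus),
                                mol_len(locus) - ip, params, "+")
    attr(flipped, "insertion_point") <- ip
    attr(flipped, "designed_on") <- "-"
    return(flipped)
  }
  fl <- params$oligo_flank_len
  flank5 <- locus_segment(locus, ip - fl, ip, "5' oligo flank")
  flank3 <- locus_segment(locus, ip, ip + fl, "3' oligo flank")
  mol <- assemble_segments(paste0(locus$id, "_loxP_oligo"), list(
    list(flank5, "homology_arm", "oligo_flank_5p"),
    list(params$loxp_seq, "loxP", "loxP"),
    list(flank3, "homology_arm", "oligo_flank_3p")
  ))
  L <- mol_len(mol)
  ps <- params$phosphorothioate_per_end
  attr(mol, "phosphorothioate_bonds") <-
    as.integer(c(seq_len(ps), L - 1L - ps + seq_len(ps)))
  attr(mol, "insertion_point") <- ip
  attr(mol, "designed_on") <- "+"
  mol
}

#' Design the retrieval (gap repair) insert
#'
#' @param locus Locus \code{dna_molecule}.
#' @param retrieve_interval Length-2 vector or list \code{(start, end)},
#'   0-based half-open: the genomic region to be retrieved from the
#'   modified BAC.
#' @param params \code{\link{design_parameters}}.
#' @return Linear \code{dna_molecule}: NotI site, 200-nt arm equal to the
#'   first 200 bases of the interval, XhoI site, 200-nt arm equal to the
#'   last 200 bases of the interval.
#' @export
design_retrieval_insert <- function(locus, retrieve_interval,
                                    params = design_parameters()) {
  iv <- as.integer(unlist(retrieve_interval))
  a <- params$retrieval_arm_len
  if (iv[2] - iv[1] < 2L * a) {
    stop("retrieve interval (", iv[2] - iv[1], " bases) is shorter than two ",
         a, "-base arms", call. = FALSE)
  }
  arm5 <- locus_segment(locus, iv[1], iv[1] + a, "5' retrieval arm")
  arm3 <- locus_segment(locus, iv[2] - a, iv[2], "3' retrieval arm")
  for (enz in c(params$retrieval_linearization_enzyme,
                params$retrieval_release_enzyme)) {
    pat <- enzyme_site(enz)
    if (grepl(pat, arm5, fixed = TRUE) || grepl(pat, arm3, fixed = TRUE)) {
      stop(enz, " site occurs inside a retrieval arm", call. = FALSE)
    }
  }
  mol <- assemble_segments(paste0(locus$id, "_retrieval_insert"), list(
    list(enzyme_site(params$retrieval_release_enzyme), "restriction_site",
         params$retrieval_release_enzyme),
    list(arm5, "homology_arm", "retrieval_arm_5p"),
    list(enzyme_site(params$retrieval_linearization_enzyme),
         "restriction_site", params$retrieval_linearization_enzyme),
    list(arm3, "homology_arm", "retrieval_arm_3p")
  ))
  attr(mol, "retrieve_interval") <- iv
  mol
}

#' Design the loxP screening primer pair
#'
#' Both primers bind outside the oligo homology arms so the 34-base loxP
#' insertion shifts the amplicon size; the predicted targeted amplicon is
#' always wild-type + 34. Selection scans outward from the arms for the
#' nearest 20-mer with 40-60\% GC that is unique in the locus (no
#' thermodynamic model).
#'
#' @param locus Locus \code{dna_molecule}.
#' @param lox_point 0-based loxP oligo insertion coordinate.
#' @param params \code{\link{design_parameters}}.
#' @param primer_len Primer length (bases).
#' @param fwd_start,rev_start Optional manual 0-based primer start
#'   positions (rev_start is the leftmost base of the reverse primer's
#'   binding site on the forward strand); validated to fall outside the
#'   oligo arms and to be unique.
#' @return List of class \code{primer_pair}: \code{fwd}, \code{rev}
#'   (5'->3' sequences), binding coordinates, \code{wt_amplicon} and
#'   \code{targeted_amplicon} lengths.
#' @export
design_screen_primers <- function(locus, lox_point,
                                  params = design_parameters(),
                                  primer_len = 20L,
                                  fwd_start = NULL, rev_start = NULL) {
  fl <- params$oligo_flank_len
  arm_lo <- as.integer(lox_point) - fl  # arms span [arm_lo, arm_hi)
  arm_hi <- as.integer(lox_point) + fl
  L <- mol_len(locus)
  pick <- function(start) substr(locus$seq, start + 1L, start + primer_len)
  is_unique <- function(s) {
    length(find_pattern(locus, s)) == 1L &&
      length(find_pattern(locus, revcomp_seq(s))) == 0L
  }
  gc_ok <- function(s) {
    gc <- nchar(gsub("[AT]", "", s)) / nchar(s)
    gc >= 0.4 && gc <= 0.6 && !grepl("N", s, fixed = TRUE)
  }
  validate_manual <- function(start, side) {
    if (start < 0L || start + primer_len > L) {
      stop(side, " primer runs off the locus", call. = FALSE)
    }
    if (start + primer_len > arm_lo && start < arm_hi) {
      stop(side, " primer falls inside the oligo homology arms", call. = FALSE)
    }
    s <- pick(start)
    if (!is_unique(s)) stop(side, " primer sequence is not unique in the locus",
                            call. = FALSE)
    start
  }
  if (!is.null(fwd_start)) {
    fwd_start <- validate_manual(as.integer(fwd_start), "forward")
  } else {
    for (s in seq(arm_lo - primer_len, 0L)) {
      cand <- pick(s)
      if (gc_ok(cand) && is_unique(cand)) { fwd_start <- s; break }
    }
    if (is.null(fwd_start)) stop("no suitable forward primer found", call. = FALSE)
  }
  if (!is.null(rev_start)) {
    rev_start <- validate_manual(as.integer(rev_start), "reverse")
  } else {
    for (s in seq(arm_hi, L - primer_len)) {
      cand <- pick(s)
      if (gc_ok(cand) && is_unique(cand)) { rev_start <- s; break }
    }
    if (is.null(rev_start)) stop("no suitable reverse primer found", call. = FALSE)
  }
  wt <- (rev_start + primer_len) - fwd_start
  structure(
    list(fwd = pick(fwd_start), rev = revcomp_seq(pick(rev_start)),
         fwd_start = fwd_start, rev_end = rev_start + primer_len,
         primer_len = as.integer(primer_len),
         wt_amplicon = as.integer(wt),
         targeted_amplicon = as.integer(wt + 34L)),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> fwd %s / rev %s; wt %d bp, targeted %d bp\n",
              x$fwd, x$rev, x$wt_amplicon, x$targeted_amplicon))
  invisible(x)
}

#' Design the full synthesis bundle for one CKO project
#'
#' Runs the strand call and all three component designs plus the screening
#' primers.
#'
#' @param locus Locus \code{dna_molecule}.
#' @param gene \code{gene_model} on the locus.
#' @param bac \code{bac_clone} carrying the locus.
#' @param lox_point 0-based loxP oligo insertion coordinate (upstream
#'   intron of the critical exon).
#' @param cassette_point 0-based cassette insertion coordinate (downstream
#'   intron).
#' @param retrieve_interval Genomic interval to retrieve (defines the ES
#'   homology arms).
#' @param params \code{\link{design_parameters}}.
#' @return List of class \code{design_bundle}: \code{cassette_insert},
#'   \code{lox_oligo} (lagging-strand oriented), \code{lox_oligo_designed}
#'   (genome-forward as designed), \code{retrieval_insert},
#'   \code{screen_primers}, \code{strand_call}, and the input coordinates.
#' @export
design_bundle <- function(locus, gene, bac, lox_point, cassette_point,
                          retrieve_interval, params = design_parameters()) {
  call <- infer_lagging_strand(bac, gene)
  oligo <- design_lox_oligo(locus, lox_point, params, gene$strand)
  structure(
    list(cassette_insert = design_cassette_insert(locus, cassette_point,
                                                  params, gene$strand),
         lox_oligo_designed = oligo,
         lox_oligo = orient_oligo(oligo, call, gene, "lagging"),
         retrieval_insert = design_retrieval_insert(locus, retrieve_interval,
                                                    params),
         screen_primers = design_screen_primers(locus, lox_point, params),
         strand_call = call,
         lox_point = as.integer(lox_point),
         cassette_point = as.integer(cassette_point),
         retrieve_interval = as.integer(unlist(retrieve_interval)),
         params = params),
    class = "design_bundle"
  )
}

#' Machine-readable design report
#'
#' All coordinates converted to 1-based inclusive for display.
#'
#' @param bundle A \code{design_bundle}.
#' @return Nested list, ready for \code{jsonlite::write_json}.
#' @export
design_report <- function(bundle) {
  p <- bundle$params
  list(
    lox_insertion_point = bundle$lox_point + 1L,
    cassette_insertion_point = bundle$cassette_point + 1L,
    retrieve_interval = c(bundle$retrieve_interval[1] + 1L,
                          bundle$retrieve_interval[2]),
    strand_call = bundle$strand_call$lagging_equals,
    strand_rationale = bundle$strand_call$rationale,
    oligo = list(length = mol_len(bundle$lox_oligo),
                 loxp_start = bundle$lox_oligo_designed$features$start[
                   bundle$lox_oligo_designed$features$kind == "loxP"] + 1L,
                 phosphorothioate_bonds =
                   attr(bundle$lox_oligo_designed, "phosphorothioate_bonds")),
    cassette_insert_length = mol_len(bundle$cassette_insert),
    retrieval_insert_length = mol_len(bundle$retrieval_insert),
    enzymes = list(cassette_5p = p$cassette_site_enzyme_5,
                   cassette_3p = p$cassette_site_enzyme_3,
                   retrieval_linearization = p$retrieval_linearization_enzyme,
                   retrieval_release = p$retrieval_release_enzyme),
    screen_primers = unclass(bundle$screen_primers)
  )
}
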