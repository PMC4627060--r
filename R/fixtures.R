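# Deterministic synthetic fixtures: random loci with embedded multi-exon
# genes, mock BAC clones (pBACe3.6-like backbone stub with Sp6/T7 ends and
# a unidirectional OriS), mock carrier plasmids, and complete end-to-end
# scenarios including an independently string-assembled expected final CKO
# vector. Every generator is a pure function of its seed.
#
# Loci default to 20 kb (not real 100-200 kb BAC scale): nothing in the
# algorithms is length-sensitive, and a locus_len override generates
# BAC-scale fixtures when wanted. BamHI/NotI/XhoI sites are scrubbed from
# generated sequence (these must be absent/unique for release and
# linearization steps) while SpeI/EcoRI/BglII occurrences stay natural so
# restriction fingerprints have realistic band counts.

SCRUB_ENZYMES <- c("BamHI", "NotI", "XhoI")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Random protein-coding sequence: ATG + non-stop codons + TAA, resampled
# until free of the scrubbed enzyme sites.
random_coding <- function(n_codons) {
  pats <- unname(vapply(SCRUB_ENZYMES, enzyme_site, character(1)))
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste0,
                      collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  repeat {
    s <- paste0("ATG",
                paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""),
                "TAA")
    if (!any(vapply(pats, function(p) grepl(p, s, fixed = TRUE), logical(1)))) {
      return(s)
    }
  }
}

# Remove occurrences of the scrubbed enzyme sites by point substitution at
# a position outside any CDS interval (the embedded coding sequence is
# generated site-free, so every remaining site has such a position).
scrub_enzyme_sites <- function(s, cds = NULL) {
  pats <- unname(vapply(SCRUB_ENZYMES, enzyme_site, character(1)))
  in_cds <- function(p) {
    if (is.null(cds) || nrow(cds) == 0L) return(FALSE)
    any(cds$start <= p & p < cds$end)
  }
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  for (iter in 1:50) {
    hits <- list()
    for (pat in pats) {
      st <- unlist(gregexpr(pat, s, fixed = TRUE))
      st <- st[st > 0L] - 1L
      if (length(st)) hits <- c(hits, lapply(st, function(x) c(x, nchar(pat))))
    }
    if (!length(hits)) return(s)
    for (h in hits) {
      pos <- h[1] + seq_len(h[2]) - 1L  # 0-based site positions
      free <- pos[!vapply(pos, in_cds, logical(1))]
      if (!length(free)) stop("cannot scrub enzyme site inside CDS",
                              call. = FALSE)
      q <- free[ceiling(length(free) / 2)]
      base <- substr(s, q + 1L, q + 1L)
      substr(s, q + 1L, q + 1L) <- cycle[[base]]
    }
  }
  stop("enzyme-site scrubbing did not converge", call. = FALSE)
}

#' Fixture specification
#'
#' @param seed Integer seed; fully determines every generated fixture.
#' @param locus_len Locus length in bases.
#' @param n_exons Number of exons in the embedded gene (>= 3).
#' @param exon_len_range Length-2 range of exon lengths.
#' @param critical_exon Gene-order index of the critical exon (internal,
#'   fully coding; its length is adjusted so its CDS is not a multiple
#'   of 3).
#' @param gc Target GC fraction.
#' @param gene_strand Strand of the embedded gene on the locus.
#' @param bac_orientation Insert orientation for mock BAC clones.
#' @param inject_rearrangement Delete a random internal interval from the
#'   BAC insert (for fingerprint-mismatch tests).
#' @return List of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed, locus_len = 20000L, n_exons = 5L,
                         exon_len_range = c(90L, 240L), critical_exon = 3L,
                         gc = 0.5, gene_strand = "+",
                         bac_orientation = "T7_to_Sp6",
                         inject_rearrangement = FALSE) {
  if (n_exons < 3L) stop("need at least 3 exons", call. = FALSE)
  if (critical_exon <= 1L || critical_exon >= n_exons) {
    stop("critical exon must be internal", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), locus_len = as.integer(locus_len),
                 n_exons = as.integer(n_exons),
                 exon_len_range = as.integer(exon_len_range),
                 critical_exon = as.integer(critical_exon), gc = gc,
                 gene_strand = gene_strand,
                 bac_orientation = bac_orientation,
                 inject_rearrangement = inject_rearrangement),
            class = "fixture_spec")
}

#' Generate a synthetic locus with an embedded multi-exon gene
#'
#' The native CDS has a valid start and stop and no internal in-frame
#' stops; internal exons are fully coding; the critical exon's CDS length
#' is forced off a multiple of 3 so its excision frameshifts. BamHI, NotI
#' and XhoI sites are scrubbed.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return List with \code{molecule} (locus with exon/CDS features) and
#'   \code{gene} (a \code{gene_model}).
#' @export
make_locus <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_exons
    exon_len <- sample(seq(spec$exon_len_range[1], spec$exon_len_range[2]),
                       n, replace = TRUE)
    # critical exon (gene order -> genomic order) must be off-frame
    crit_row <- if (spec$gene_strand == "+") spec$critical_exon else
      n - spec$critical_exon + 1L
    if (exon_len[crit_row] %% 3L == 0L) {
      exon_len[crit_row] <- exon_len[crit_row] + 1L
    }
    intron_len <- sample(700:1200, n - 1L, replace = TRUE)
    span <- sum(exon_len) + sum(intron_len)
    if (span + 600L > spec$locus_len) {
      stop("locus too short for the requested gene", call. = FALSE)
    }
    gstart <- (spec$locus_len - span) %/% 2L
    starts <- gstart + c(0L, cumsum(exon_len[-n] + intron_len))
    exons <- data.frame(start = starts, end = starts + exon_len)
    # CDS: first exon from +30, internal exons fully coding, last exon up
    # to a length that makes the total a multiple of 3
    utr5 <- 30L
    cds <- exons
    cds$start[1] <- cds$start[1] + utr5
    last_core <- sum(cds$end[-n] - cds$start[-n])
    r <- min(90L, exon_len[n] - 30L)
    r <- r - ((last_core + r) %% 3L)
    cds$end[n] <- cds$start[n] + r
    if (spec$gene_strand == "-") {
      # mirror the UTR arrangement: exon 1 in gene order is the rightmost
      cds <- exons
      cds$end[n] <- cds$end[n] - utr5
      first_core <- sum(cds$end[-1] - cds$start[-1])
      r <- min(90L, exon_len[1] - 30L)
      r <- r - ((first_core + r) %% 3L)
      cds$start[1] <- cds$end[1] - r
    }
    base <- random_dna(spec$locus_len, spec$gc)
    total_cds <- sum(cds$end - cds$start)
    coding <- random_coding(total_cds %/% 3L)
    genomic_cds <- if (spec$gene_strand == "+") coding else revcomp_seq(coding)
    off <- 0L
    for (i in seq_len(n)) {
      w <- cds$end[i] - cds$start[i]
      substr(base, cds$start[i] + 1L, cds$end[i]) <-
        substr(genomic_cds, off + 1L, off + w)
      off <- off + w
    }
    base <- scrub_enzyme_sites(base, cds)
    gene <- gene_model(sprintf("synthgene%d", spec$seed), spec$gene_strand,
                       exons, cds, spec$critical_exon)
    mol <- dna_molecule(sprintf("synthlocus%d", spec$seed), base, "linear",
                        gene_features(gene))
    list(molecule = mol, gene = gene)
  })
}

#' Mock pBACe3.6-like backbone stub
#'
#' ~3 kb of random sequence carrying Sp6/T7 promoter-end markers and the
#' OriS origin with its replication-direction annotation (the fork moves
#' from OriS in the Sp6 transcription direction, i.e. Sp6 toward T7). Only
#' the orientation metadata is consumed by the strand logic.
#'
#' @param seed Integer seed.
#' @param len Backbone length.
#' @return Linear \code{dna_molecule} (assembled into a circle by
#'   \code{\link{bac_clone}}).
#' @export
make_mock_backbone <- function(seed, len = 3000L) {
  with_seed(seed, {
    s <- scrub_enzyme_sites(random_dna(len))
    dna_molecule(
      "mock_pBACe3.6", s, "linear",
      feature_table(
        c("promoter_end", "origin", "marker", "promoter_end"),
        c(0L, 1000L, 1000L, len - 20L),
        c(20L, 1130L, 1130L, len),
        c("+", "+", "+", "+"),
        c("Sp6_end", "OriS", "replication_direction:Sp6_toward_T7", "T7_end")
      )
    )
  })
}

# Delete [start, end) from a linear molecule, dropping straddling features.
delete_interval <- function(mol, start, end) {
  w <- end - start
  f <- rbind(features_fully_within(mol$features, 0L, start),
             shift_features(features_fully_within(mol$features, end,
                                                  mol_len(mol)), -w))
  dna_molecule(mol$id, paste0(substr(mol$seq, 1L, start),
                              substr(mol$seq, end + 1L, mol_len(mol))),
               mol$topology, f)
}

#' Mock BAC clone carrying a locus
#'
#' @param locus Locus \code{dna_molecule} (genome-forward).
#' @param orientation \code{"T7_to_Sp6"} or \code{"Sp6_to_T7"}.
#' @param seed Integer seed (backbone and optional rearrangement).
#' @param inject_rearrangement Delete a random 500-2000 base internal
#'   interval from the insert, emulating a rearranged library clone.
#' @return A \code{\link{bac_clone}}.
#' @export
make_mock_bac <- function(locus, orientation = "T7_to_Sp6", seed = 1L,
                          inject_rearrangement = FALSE) {
  backbone <- make_mock_backbone(seed)
  insert <- locus
  if (inject_rearrangement) {
    insert <- with_seed(seed + 101L, {
      w <- sample(500:2000, 1L)
      st <- sample(seq(100L, mol_len(locus) - w - 100L), 1L)
      delete_interval(locus, st, st + w)
    })
  }
  bac_clone(sprintf("mockBAC_%s_%d", orientation, seed), insert, orientation,
            backbone)
}

#' Mock PL452-style neo fragment
#'
#' A 1.9 kb dual-selection cassette stand-in: the Pgk1-5' homology, a
#' random core annotated as the Pgk1-em7-neo-BGHpA marker, and the
#' BGHpA-3' homology. Its terminal homologies recombine with the
#' synthesized cassette insert.
#'
#' @param seed Integer seed.
#' @param params \code{\link{design_parameters}}.
#' @param len Total fragment length.
#' @return Linear \code{dna_molecule}.
#' @export
make_neo_fragment <- function(seed, params = design_parameters(),
                              len = 1900L) {
  with_seed(seed, {
    core_len <- len - nchar(params$pgk1_seq) - nchar(params$bghpa_seq)
    core <- scrub_enzyme_sites(random_dna(core_len))
    assemble_segments("PL452_neo_fragment", list(
      list(params$pgk1_seq, "marker", "Pgk1_5p_homology"),
      list(core, "marker", "Pgk1-em7-neo-BGHpA"),
      list(params$bghpa_seq, "marker", "BGHpA_3p_homology")
    ))
  })
}

#' Mock pUC carrier plasmid holding the synthesized cassette insert
#'
#' @param cassette_insert The designed cassette insert molecule.
#' @param seed Integer seed (backbone sequence).
#' @param backbone_len Backbone length (pUC-scale).
#' @return Circular \code{dna_molecule}.
#' @export
make_puc_carrier <- function(cassette_insert, seed, backbone_len = 2686L) {
  with_seed(seed, {
    bb <- scrub_enzyme_sites(random_dna(backbone_len))
    feats <- rbind(
      feature_table(c("marker", "origin"), c(100L, 1400L), c(960L, 2000L),
                    c("+", "+"), c("AmpR", "pUC_ori")),
      shift_features(cassette_insert$features, backbone_len)
    )
    dna_molecule("pUC_cassette_plasmid",
                 paste0(bb, cassette_insert$seq), "circular", feats)
  })
}

#' Mock pBlight-TK retrieval vector holding the synthesized retrieval insert
#'
#' @param retrieval_insert The designed retrieval insert molecule.
#' @param seed Integer seed (backbone sequence).
#' @param backbone_len Backbone length.
#' @return Circular \code{dna_molecule} (linearize at the XhoI site
#'   between the arms before gap repair).
#' @export
make_retrieval_vector <- function(retrieval_insert, seed,
                                  backbone_len = 4300L) {
  with_seed(seed, {
    bb <- scrub_enzyme_sites(random_dna(backbone_len))
    feats <- rbind(
      feature_table(c("marker", "marker", "origin"),
                    c(100L, 1500L, 2600L), c(1300L, 2460L, 3200L),
                    c("+", "+", "+"), c("HSV_TK", "AmpR", "ori")),
      shift_features(retrieval_insert$features, backbone_len)
    )
    dna_molecule("pBlightTK_retrieval",
                 paste0(bb, retrieval_insert$seq), "circular", feats)
  })
}

#' Complete end-to-end scenario bundle
#'
#' Generates a locus + gene (critical exon off-frame by construction), a
#' mock BAC, the full design bundle, the mock carrier molecules, and the
#' independently string-assembled expected final CKO vector (the
#' brute-force oracle for pipeline equivalence).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to \code{\link{fixture_spec}}.
#' @param params \code{\link{design_parameters}}.
#' @param arm_target Intended ES homology arm length (distance from each
#'   insertion point to its retrieval boundary).
#' @return Named list: \code{spec}, \code{locus}, \code{gene}, \code{bac},
#'   \code{bundle}, \code{neo_fragment}, \code{puc_carrier},
#'   \code{retrieval_vector}, \code{expected_cko}, and the design
#'   coordinates.
#' @export
make_end_to_end_fixture <- function(seed, ..., params = design_parameters(),
                                    arm_target = 3000L) {
  spec <- fixture_spec(seed = seed, ...)
  lx <- make_locus(spec)
  locus <- lx$molecule
  gene <- lx$gene
  crit <- exon_interval(gene, spec$critical_exon)
  # loxP oligo goes in the intron 5' of the critical exon (gene
  # orientation); the cassette in the 3' intron
  if (gene$strand == "+") {
    lox_point <- crit$start - 250L
    cassette_point <- crit$end + 250L
  } else {
    lox_point <- crit$end + 250L
    cassette_point <- crit$start - 250L
  }
  retrieve_interval <- c(min(lox_point, cassette_point) - arm_target,
                         max(lox_point, cassette_point) + arm_target)
  if (retrieve_interval[1] < 0L || retrieve_interval[2] > mol_len(locus)) {
    stop("locus too short for the requested ES homology arms", call. = FALSE)
  }
  bac <- make_mock_bac(locus, spec$bac_orientation, seed = spec$seed + 1L,
                       inject_rearrangement = spec$inject_rearrangement)
  bundle <- design_bundle(locus, gene, bac, lox_point, cassette_point,
                          retrieve_interval, params)
  neo <- make_neo_fragment(spec$seed + 2L, params)
  puc <- make_puc_carrier(bundle$cassette_insert, spec$seed + 3L)
  retr <- make_retrieval_vector(bundle$retrieval_insert, spec$seed + 4L)

  # ---- brute-force oracle: direct string assembly of the final vector ----
  cass_payload <- paste0(params$frt_seq, neo$seq, params$frt_seq,
                         params$spacer_seq, params$loxp_seq)
  lox_ins <- params$loxp_seq
  if (gene$strand == "-") {
    # components are designed in gene orientation; their genome-forward
    # representation is the reverse complement
    cass_payload <- revcomp_seq(cass_payload)
    lox_ins <- revcomp_seq(lox_ins)
  }
  q1 <- min(lox_point, cassette_point)
  q2 <- max(lox_point, cassette_point)
  ins1 <- if (q1 == lox_point) lox_ins else cass_payload
  ins2 <- if (q2 == cassette_point) cass_payload else lox_ins
  modified_genomic <- paste0(
    substr(locus$seq, retrieve_interval[1] + 1L, q1), ins1,
    substr(locus$seq, q1 + 1L, q2), ins2,
    substr(locus$seq, q2 + 1L, retrieve_interval[2])
  )
  backbone_seq <- substr(retr$seq, 1L, mol_len(retr) -
                           mol_len(bundle$retrieval_insert))
  expected_cko <- dna_molecule(
    "expected_cko_vector",
    paste0(modified_genomic, backbone_seq,
           enzyme_site(params$retrieval_release_enzyme)),
    "circular"
  )

  list(spec = spec, locus = locus, gene = gene, bac = bac, bundle = bundle,
       neo_fragment = neo, puc_carrier = puc, retrieval_vector = retr,
       expected_cko = expected_cko, lox_point = lox_point,
       cassette_point = cassette_point,
       retrieve_interval = retrieve_interval, params = params)
}
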