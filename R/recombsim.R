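# In-silico DNA transactions: homology-directed replacement/insertion
# (double-stranded cassette or single-stranded oligo), gap-repair
# retrieval, Cre/Flp site-specific recombination, restriction digestion,
# PCR, and restriction-fingerprint comparison.
#
# Homology matching is exact-substring only and must be unique; ambiguity
# is an error, never a choice. Terminal bases of a donor that do not match
# the target (e.g. restriction-site remnants on a released cassette or a
# linearized retrieval vector) are tolerated up to `end_slack` bases and
# dropped from the product; the junction trace records them.

# ---- feature bookkeeping helpers -------------------------------------------

features_fully_within <- function(f, lo, hi) {
  f[f$start >= lo & f$end <= hi & f$start < f$end, , drop = FALSE]
}

shift_features <- function(f, delta) {
  if (nrow(f)) {
    f$start <- f$start + as.integer(delta)
    f$end <- f$end + as.integer(delta)
  }
  f
}

# Rotate a circular molecule only when one of the listed features wraps
# the origin (so downstream arithmetic can assume contiguous features).
# No-op for linear molecules and when nothing wraps.
rotate_clear_of <- function(mol, feats) {
  if (mol$topology != "circular" || nrow(feats) == 0L) return(mol)
  wraps <- which(feats$start > feats$end)
  if (length(wraps) == 0L) return(mol)
  rotate_molecule(mol, feats$end[wraps[1]])
}

target_base <- function(mol, i) {
  L <- mol_len(mol)
  if (mol$topology == "circular") i <- i %% L
  if (i < 0L || i >= L) return(NA_character_)
  substr(mol$seq, i + 1L, i + 1L)
}

# ---- terminal arm location -------------------------------------------------

# Locate one terminal homology arm of `donor_seq` on `target`.
# Returns NULL when no seed (at any slack offset) matches; stops on
# ambiguous seeds. On success returns 0-based donor/target intervals of the
# maximally extended exact match.
find_terminal_arm <- function(target, donor_seq, side = c("5", "3"),
                              min_arm, end_slack) {
  side <- match.arg(side)
  Ld <- nchar(donor_seq)
  for (off in 0:end_slack) {
    if (min_arm + off > Ld) break
    seed <- if (side == "5") {
      substr(donor_seq, off + 1L, off + min_arm)
    } else {
      substr(donor_seq, Ld - off - min_arm + 1L, Ld - off)
    }
    starts <- find_pattern(target, seed)
    if (length(starts) == 0L) next
    if (length(starts) > 1L) {
      stop("homology arm seed matches the target at multiple positions: ",
           paste(starts + 1L, collapse = ", "), call. = FALSE)
    }
    t0 <- starts[1]
    if (side == "5") {
      k <- min_arm
      while (off + k < Ld) {
        b <- target_base(target, t0 + k)
        if (is.na(b) || b != substr(donor_seq, off + k + 1L, off + k + 1L)) break
        k <- k + 1L
      }
      return(list(donor_start = off, donor_end = off + k,
                  target_start = t0, target_end = t0 + k))
    } else {
      ext <- 0L
      a <- Ld - off - min_arm  # 0-based donor arm start
      while (a - ext > 0L) {
        b <- target_base(target, t0 - ext - 1L)
        if (is.na(b) ||
            b != substr(donor_seq, a - ext, a - ext)) break
        ext <- ext + 1L
      }
      return(list(donor_start = a - ext, donor_end = Ld - off,
                  target_start = t0 - ext, target_end = t0 + min_arm))
    }
  }
  NULL
}

# Resolve donor orientation: both terminal arms must be found on the same
# strand of the target. Returns list(donor = oriented molecule, m5, m3,
# flipped).
orient_donor <- function(target, donor, min_arm, end_slack) {
  try_both <- function(d) {
    list(m5 = find_terminal_arm(target, d$seq, "5", min_arm, end_slack),
         m3 = find_terminal_arm(target, d$seq, "3", min_arm, end_slack))
  }
  fwd <- try_both(donor)
  if (!is.null(fwd$m5) && !is.null(fwd$m3)) {
    return(list(donor = donor, m5 = fwd$m5, m3 = fwd$m3, flipped = FALSE))
  }
  rc <- reverse_complement(donor)
  rev <- try_both(rc)
  if (!is.null(rev$m5) && !is.null(rev$m3)) {
    return(list(donor = rc, m5 = rev$m5, m3 = rev$m3, flipped = TRUE))
  }
  found_any <- !is.null(fwd$m5) || !is.null(fwd$m3) ||
    !is.null(rev$m5) || !is.null(rev$m3)
  if (found_any) {
    stop("homology arms found in inconsistent orientation on the target",
         call. = FALSE)
  }
  stop("homology arm not found in the target", call. = FALSE)
}

# ---- recombineering --------------------------------------------------------

recombineer_engine <- function(target, donor, min_arm, end_slack) {
  ori <- orient_donor(target, donor, min_arm, end_slack)
  donor <- ori$donor
  if (target$topology == "circular") {
    # rotate so the 5' arm match starts at the origin; all arithmetic is
    # then linear (rotation invariance of the product is a tested property)
    target <- rotate_molecule(target, ori$m5$target_start)
    ori$m3$target_start <- ori$m3$target_start - ori$m5$target_start
    ori$m3$target_end <- ori$m3$target_end - ori$m5$target_start
    ori$m5$target_end <- ori$m5$target_end - ori$m5$target_start
    ori$m5$target_start <- 0L
    L <- mol_len(target)
    ori$m3$target_start <- ori$m3$target_start %% L
    ori$m3$target_end <- ((ori$m3$target_end - 1L) %% L) + 1L
  }
  m5 <- ori$m5
  m3 <- ori$m3
  if (m3$target_end < m5$target_start) {
    stop("homology arms match the target in inconsistent order", call. = FALSE)
  }
  L <- mol_len(target)
  span <- m3$target_end - m5$target_start
  payload <- substr(donor$seq, m5$donor_start + 1L, m3$donor_end)
  pre <- substr(target$seq, 1L, m5$target_start)
  post <- substr(target$seq, m3$target_end + 1L, L)
  delta <- nchar(payload) - span

  f_pre <- features_fully_within(target$features, 0L, m5$target_start)
  f_post <- shift_features(
    features_fully_within(target$features, m3$target_end, L), delta
  )
  f_payload <- shift_features(
    features_fully_within(donor$features, m5$donor_start, m3$donor_end),
    m5$target_start - m5$donor_start
  )
  arm5_len <- m5$donor_end - m5$donor_start
  arm3_len <- m3$donor_end - m3$donor_start
  f_junction <- feature_table(
    c("homology_arm", "homology_arm"),
    c(m5$target_start, m5$target_start + nchar(payload) - arm3_len),
    c(m5$target_start + arm5_len, m5$target_start + nchar(payload)),
    c("+", "+"), c("junction_5p", "junction_3p")
  )
  product <- dna_molecule(paste0(target$id, "_recombined"),
                          paste0(pre, payload, post), target$topology,
                          rbind(f_pre, f_payload, f_junction, f_post))
  attr(product, "trace") <- list(
    op = "recombineer",
    donor_flipped = ori$flipped,
    arm5 = m5, arm3 = m3,
    replaced_span = span, payload_len = nchar(payload),
    dropped_donor_5p = m5$donor_start,
    dropped_donor_3p = mol_len(donor) - m3$donor_end
  )
  product
}

#' Simulate double-stranded cassette recombineering
#'
#' The target region between (and including) the two terminal arm matches
#' is replaced by the donor cassette; product length equals
#' \code{len(target) - replaced_span + payload_len}. Arms must match the
#' target exactly, uniquely, and in consistent orientation and order.
#'
#' @param target Target \code{dna_molecule} (plasmid or BAC; linear or
#'   circular).
#' @param cassette Donor \code{dna_molecule}.
#' @param min_arm Minimum terminal homology (bases) used to seed matching.
#' @param end_slack Maximum unmatched terminal bases tolerated (e.g.
#'   restriction-site remnants); dropped from the product and recorded in
#'   the junction trace.
#' @return Product \code{dna_molecule} with remapped features, junction
#'   \code{homology_arm} features, and a \code{"trace"} attribute.
#' @export
recombineer_ds <- function(target, cassette, min_arm = 50L, end_slack = 20L) {
  recombineer_engine(target, cassette, as.integer(min_arm),
                     as.integer(end_slack))
}

#' Simulate single-stranded oligo recombineering
#'
#' Identical product semantics to \code{\link{recombineer_ds}}: the payload
#' between the oligo flanks is inserted (flanks matching adjacently) or
#' replaces the spanned interval. The product is independent of which
#' strand version of the oligo is supplied; strand choice matters only for
#' in-vivo efficiency, which is not simulated.
#'
#' @param target Target \code{dna_molecule}.
#' @param oligo The single-stranded donor oligo.
#' @inheritParams recombineer_ds
#' @return Product \code{dna_molecule}.
#' @export
recombineer_ss <- function(target, oligo, min_arm = 50L, end_slack = 20L) {
  recombineer_engine(target, oligo, as.integer(min_arm), as.integer(end_slack))
}

# ---- gap repair ------------------------------------------------------------

#' Simulate gap-repair retrieval into a linearized vector
#'
#' The linearized vector's terminal arms anneal to the two ends of a unique
#' interval on the (modified) BAC; the interval between the arm matches is
#' copied into the vector, producing a circular plasmid in which each arm
#' appears exactly once. The product is rotated so the retrieved genomic
#' region starts at the origin.
#'
#' @param bac A \code{bac_clone} or the BAC \code{dna_molecule}.
#' @param linearized_vector Linear \code{dna_molecule} (e.g. an
#'   XhoI-linearized retrieval vector).
#' @inheritParams recombineer_ds
#' @return Circular \code{dna_molecule}; features inside the retrieved
#'   interval are carried over, and \code{homology_arm} features labelled
#'   \code{retrieval_arm_genomic_5p}/\code{_3p} mark the junctions. The
#'   \code{"trace"} attribute records the retrieved interval.
#' @export
gap_repair <- function(bac, linearized_vector, min_arm = 50L,
                       end_slack = 20L) {
  target <- if (inherits(bac, "bac_clone")) bac$molecule else bac
  if (linearized_vector$topology != "linear") {
    stop("retrieval vector must be linearized before gap repair", call. = FALSE)
  }
  min_arm <- as.integer(min_arm)
  end_slack <- as.integer(end_slack)
  ori <- orient_donor(target, linearized_vector, min_arm, end_slack)
  vec <- ori$donor
  a <- ori$m5  # vector 5'-terminal arm
  b <- ori$m3  # vector 3'-terminal arm
  L <- mol_len(target)
  overlap <- !(a$target_end <= b$target_start || b$target_end <= a$target_start)
  if (overlap) {
    stop("retrieval arms match overlapping target positions (degenerate ",
         "interval)", call. = FALSE)
  }
  mid_len <- (a$target_start - b$target_end) %% L
  if (target$topology == "linear") {
    if (b$target_end > a$target_start) {
      stop("retrieval arms face outward on a linear target", call. = FALSE)
    }
    mid_len <- a$target_start - b$target_end
  }
  middle <- subseq_circular(target$seq, b$target_end, b$target_end + mid_len)
  retained <- substr(vec$seq, a$donor_start + 1L, b$donor_end)
  # pre-rotation product: [ARM_A ... vector body ... ARM_B][middle]
  seq0 <- paste0(retained, middle)

  f_vec <- shift_features(
    features_fully_within(vec$features, a$donor_start, b$donor_end),
    -a$donor_start
  )
  # target features fully inside the retrieved middle
  tf <- target$features
  keep <- logical(nrow(tf))
  map <- integer(nrow(tf))
  for (i in seq_len(nrow(tf))) {
    rel <- (tf$start[i] - b$target_end) %% L
    if (target$topology == "linear") rel <- tf$start[i] - b$target_end
    w <- feature_lengths(tf[i, , drop = FALSE], L)
    if (rel >= 0L && rel + w <= mid_len) {
      keep[i] <- TRUE
      map[i] <- rel
    }
  }
  f_mid <- tf[keep, , drop = FALSE]
  if (nrow(f_mid)) {
    w <- feature_lengths(f_mid, L)
    f_mid$start <- as.integer(nchar(retained) + map[keep])
    f_mid$end <- as.integer(f_mid$start + w)
  }
  armA_len <- a$donor_end - a$donor_start
  armB_len <- b$donor_end - b$donor_start
  posB <- b$donor_start - a$donor_start
  f_junction <- feature_table(
    c("homology_arm", "homology_arm"),
    c(posB, 0L), c(posB + armB_len, armA_len), c("+", "+"),
    c("retrieval_arm_genomic_5p", "retrieval_arm_genomic_3p")
  )
  product <- dna_molecule(paste0(target$id, "_retrieved"), seq0, "circular",
                          rbind(f_vec, f_junction, f_mid))
  # rotate so the retrieved genomic region (5' arm + middle + 3' arm) is
  # contiguous from the origin
  product <- rotate_molecule(product, posB)
  attr(product, "trace") <- list(
    op = "gap_repair", donor_flipped = ori$flipped,
    retrieved_len = armB_len + mid_len + armA_len,
    middle_len = mid_len,
    dropped_vector_5p = a$donor_start,
    dropped_vector_3p = mol_len(linearized_vector) - b$donor_end
  )
  product
}

# ---- site-specific recombination -------------------------------------------

#' Simulate Cre/Flp site-specific recombination
#'
#' Recombination between two sites of the given kind, crossing over at the
#' site midpoints so each product carries one full 34-nt site. Directly
#' repeated sites excise the intervening segment (circular input: two
#' circles, one site each; linear input: a shortened linear molecule plus
#' an excised circle). Inverted sites invert the intervening segment,
#' retaining both sites.
#'
#' @param mol A \code{dna_molecule} carrying the sites as features.
#' @param site_kind \code{"loxP"} or \code{"FRT"}.
#' @param pair When more than two sites are present, the 1-based indices
#'   (in position order) of the pair to recombine.
#' @return For excision, a named list with \code{retained} and
#'   \code{excised} molecules; for inversion, a one-element list
#'   \code{inverted}.
#' @export
site_specific_recombine <- function(mol, site_kind = c("loxP", "FRT"),
                                    pair = NULL) {
  site_kind <- match.arg(site_kind)
  sites <- features_of(mol, site_kind)
  if (nrow(sites) < 2L) {
    stop("need at least two ", site_kind, " sites, found ", nrow(sites),
         call. = FALSE)
  }
  if (nrow(sites) > 2L && is.null(pair)) {
    stop(nrow(sites), " ", site_kind,
         " sites present; specify `pair` to choose two", call. = FALSE)
  }
  mol <- rotate_clear_of(mol, sites)
  sites <- features_of(mol, site_kind)
  if (!is.null(pair)) sites <- sites[pair, , drop = FALSE]
  sites <- sites[order(sites$start), , drop = FALSE]
  s1 <- sites[1, ]
  s2 <- sites[2, ]
  L <- mol_len(mol)
  mid1 <- s1$start + 17L
  mid2 <- s2$start + 17L
  f <- mol$features
  drop_these <- !(f$kind == site_kind &
                    (f$start %in% c(s1$start, s2$start)))
  f <- f[drop_these, , drop = FALSE]

  if (s1$strand == s2$strand) {
    # --- excision ---
    # excised circle: s2-left-half + s1-right-half + intervening
    ex_seq <- paste0(substr(mol$seq, s2$start + 1L, mid2),
                     substr(mol$seq, mid1 + 1L, mid2 - 17L))
    ex_f <- features_fully_within(f, s1$end, s2$start)
    if (nrow(ex_f)) ex_f <- shift_features(ex_f, 34L - s1$end)
    ex_f <- rbind(feature(site_kind, 0L, 34L, s1$strand,
                          paste0(site_kind, "_hybrid")), ex_f)
    excised <- dna_molecule(paste0(mol$id, "_excised"), ex_seq, "circular",
                            ex_f)
    if (mol$topology == "circular") {
      # retained circle: s1-left-half + s2-right-half + outside segment
      ret_seq <- paste0(substr(mol$seq, mid1 - 16L, mid1),
                        substr(mol$seq, mid2 + 1L, L),
                        substr(mol$seq, 1L, mid1 - 17L))
      f_right <- features_fully_within(f, s2$end, L)
      if (nrow(f_right)) f_right <- shift_features(f_right, 34L - s2$end)
      f_left <- features_fully_within(f, 0L, s1$start)
      if (nrow(f_left)) f_left <- shift_features(f_left, 34L + (L - s2$end))
      ret_f <- rbind(feature(site_kind, 0L, 34L, s1$strand,
                             paste0(site_kind, "_hybrid")), f_right, f_left)
      retained <- dna_molecule(paste0(mol$id, "_recombined"), ret_seq,
                               "circular", ret_f)
    } else {
      ret_seq <- paste0(substr(mol$seq, 1L, mid1), substr(mol$seq, mid2 + 1L, L))
      f_left <- features_fully_within(f, 0L, s1$start)
      f_right <- shift_features(features_fully_within(f, s2$end, L),
                                -(mid2 - mid1))
      ret_f <- rbind(f_left,
                     feature(site_kind, s1$start, s1$start + 34L, s1$strand,
                             paste0(site_kind, "_hybrid")),
                     f_right)
      retained <- dna_molecule(paste0(mol$id, "_recombined"), ret_seq,
                               "linear", ret_f)
    }
    list(retained = retained, excised = excised)
  } else {
    # --- inversion ---
    inner <- substr(mol$seq, mid1 + 1L, mid2)
    new_seq <- paste0(substr(mol$seq, 1L, mid1), revcomp_seq(inner),
                      substr(mol$seq, mid2 + 1L, L))
    f_out <- rbind(features_fully_within(f, 0L, mid1 - 17L),
                   features_fully_within(f, mid2 + 17L, L))
    f_in <- features_fully_within(f, s1$end, s2$start)
    if (nrow(f_in)) {
      ns <- mid1 + (mid2 - f_in$end)
      ne <- mid1 + (mid2 - f_in$start)
      f_in$start <- as.integer(ns)
      f_in$end <- as.integer(ne)
      f_in$strand <- ifelse(f_in$strand == "+", "-", "+")
    }
    f_sites <- feature_table(
      c(site_kind, site_kind), c(s1$start, s2$start),
      c(s1$start + 34L, s2$start + 34L), c(s1$strand, s2$strand),
      paste0(site_kind, c("_hybrid_1", "_hybrid_2"))
    )
    list(inverted = dna_molecule(paste0(mol$id, "_inverted"), new_seq,
                                 mol$topology,
                                 rbind(f_out, f_sites, f_in)))
  }
}

# ---- restriction digestion -------------------------------------------------

#' Simulate a restriction digest
#'
#' Cut position is the 5' end of the recognition site. A linear molecule
#' with n cuts yields n+1 fragments; a circular molecule with n >= 1 cuts
#' yields n fragments; fragment lengths always sum to the molecule length.
#'
#' @param mol A \code{dna_molecule}.
#' @param enzymes Character vector of enzyme names from
#'   \code{\link{restriction_enzymes}}.
#' @return Object of class \code{digest_result}: \code{enzymes},
#'   \code{cuts} (0-based), \code{fragments} (list of molecules),
#'   \code{lengths}, \code{topology}.
#' @export
digest <- function(mol, enzymes) {
  pats <- vapply(enzymes, enzyme_site, character(1))
  cuts <- sort(unique(unlist(lapply(pats, function(p) find_pattern(mol, p)))))
  L <- mol_len(mol)
  if (mol$topology == "linear") {
    cuts <- cuts[cuts > 0L & cuts < L]
    bounds <- c(0L, cuts, L)
    frags <- lapply(seq_len(length(bounds) - 1L), function(i) {
      lo <- bounds[i]
      hi <- bounds[i + 1L]
      dna_molecule(paste0(mol$id, "_frag", i),
                   substr(mol$seq, lo + 1L, hi), "linear",
                   shift_features(features_fully_within(mol$features, lo, hi),
                                  -lo))
    })
  } else if (length(cuts) == 0L) {
    frags <- list(mol)
  } else {
    frags <- lapply(seq_along(cuts), function(i) {
      lo <- cuts[i]
      hi <- if (i < length(cuts)) cuts[i + 1L] else cuts[1] + L
      rot <- rotate_molecule(mol, lo)
      n <- hi - lo
      dna_molecule(paste0(mol$id, "_frag", i),
                   substr(rot$seq, 1L, n), "linear",
                   features_fully_within(rot$features, 0L, n))
    })
  }
  lens <- vapply(frags, mol_len, integer(1))
  stopifnot(sum(lens) == L)
  structure(list(enzymes = enzymes, cuts = cuts, fragments = frags,
                 lengths = sort(lens), topology = mol$topology),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s on %s molecule: %d fragment(s): %s\n",
              paste(x$enzymes, collapse = "+"), x$topology,
              length(x$lengths), paste(x$lengths, collapse = ", ")))
  invisible(x)
}

#' Linearize a circular molecule at a unique enzyme site
#'
#' @param mol Circular \code{dna_molecule}.
#' @param enzyme Enzyme name; must cut exactly once.
#' @return Linear \code{dna_molecule} starting at the cut.
#' @export
linearize <- function(mol, enzyme) {
  if (mol$topology != "circular") stop("molecule is already linear",
                                       call. = FALSE)
  d <- digest(mol, enzyme)
  if (length(d$cuts) != 1L) {
    stop(enzyme, " cuts ", length(d$cuts), " time(s); need exactly one site",
         call. = FALSE)
  }
  d$fragments[[1]]
}

#' Release the targeting cassette from its carrier plasmid
#'
#' Digests with the release enzyme and returns the fragment carrying the
#' FRT sites (the size-shifted cassette).
#'
#' @param plasmid Carrier plasmid \code{dna_molecule} after the neo
#'   cassette has been inserted.
#' @param enzyme Release enzyme name.
#' @return Linear \code{dna_molecule}.
#' @export
release_cassette <- function(plasmid, enzyme) {
  d <- digest(plasmid, enzyme)
  has_frt <- vapply(d$fragments, function(fr) nrow(features_of(fr, "FRT")) > 0L,
                    logical(1))
  if (sum(has_frt) != 1L) {
    stop("expected exactly one FRT-carrying fragment, found ", sum(has_frt),
         call. = FALSE)
  }
  d$fragments[[which(has_frt)]]
}

# ---- PCR -------------------------------------------------------------------

amplicons_one <- function(mol, fwd, rev, max_amplicon) {
  L <- mol_len(mol)
  lens <- integer()
  for (cfg in 1:2) {
    p1 <- if (cfg == 1L) fwd else rev
    p2 <- if (cfg == 1L) rev else fwd
    f_hits <- find_pattern(mol, p1)
    r_hits <- find_pattern(mol, revcomp_seq(p2))
    for (fh in f_hits) {
      for (rh in r_hits) {
        end <- rh + nchar(p2)
        if (mol$topology == "circular") {
          l <- ((end - fh - 1L) %% L) + 1L
          if (l >= nchar(p1) + nchar(p2) && l <= max_amplicon) {
            lens <- c(lens, l)
          }
        } else {
          l <- end - fh
          if (end > fh && l >= nchar(p1) + nchar(p2) && l <= max_amplicon) {
            lens <- c(lens, l)
          }
        }
      }
    }
  }
  sort(unique(lens))
}

#' Predict PCR amplicons
#'
#' Exact-match primer binding with no thermodynamic model: one amplicon per
#' convergent primer pair within \code{max_amplicon}. On circular
#' templates, amplicons may span the origin. Supplying a list of templates
#' models a polyclonal well: the union of amplicon lengths is returned
#' (the two-band pattern of a mixed well).
#'
#' @param templates A \code{dna_molecule} or list of them.
#' @param fwd,rev Primer sequences, 5'->3', each at least 15 nt.
#' @param max_amplicon Longest product considered (bases).
#' @return Sorted integer vector of amplicon lengths (empty when no
#'   product); warns when a single template yields more than one product.
#' @export
pcr <- function(templates, fwd, rev, max_amplicon = 5000L) {
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  if (inherits(templates, "dna_molecule")) templates <- list(templates)
  all_lens <- integer()
  for (mol in templates) {
    lens <- amplicons_one(mol, toupper(fwd), toupper(rev),
                          as.integer(max_amplicon))
    if (length(lens) > 1L) {
      warning("template ", mol$id, " yields ", length(lens), " amplicons")
    }
    all_lens <- c(all_lens, lens)
  }
  sort(unique(all_lens))
}

# ---- fragment-set comparison (fingerprinting) ------------------------------

#' Compare restriction fragment size sets
#'
#' Greedy size matching within a relative tolerance, for checking BAC
#' integrity against a reference fingerprint (e.g. SpeI).
#'
#' @param observed,expected Numeric vectors of fragment lengths.
#' @param tolerance Relative size tolerance (fraction of the expected
#'   fragment size).
#' @return Object of class \code{fragment_match}: \code{matches} (data
#'   frame), \code{unmatched_observed}, \code{unmatched_expected}, and
#'   logical \code{identical_within_tolerance}.
#' @export
compare_fragment_sets <- function(observed, expected, tolerance = 0.05) {
  observed <- sort(as.numeric(observed), decreasing = TRUE)
  expected <- sort(as.numeric(expected), decreasing = TRUE)
  used <- logical(length(expected))
  m_obs <- numeric()
  m_exp <- numeric()
  un_obs <- numeric()
  for (o in observed) {
    rel <- abs(o - expected) / expected
    rel[used] <- Inf
    j <- which.min(rel)
    if (length(expected) && is.finite(rel[j]) && rel[j] <= tolerance) {
      used[j] <- TRUE
      m_obs <- c(m_obs, o)
      m_exp <- c(m_exp, expected[j])
    } else {
      un_obs <- c(un_obs, o)
    }
  }
  structure(list(
    matches = data.frame(observed = m_obs, expected = m_exp,
                         rel_diff = if (length(m_obs))
                           abs(m_obs - m_exp) / m_exp else numeric()),
    unmatched_observed = un_obs,
    unmatched_expected = expected[!used],
    identical_within_tolerance = length(un_obs) == 0L && all(used)
  ), class = "fragment_match")
}

#' @export
print.fragment_match <- function(x, ...) {
  cat(sprintf("<fragment_match> %d matched, %d observed-only, %d expected-only (%s)\n",
              nrow(x$matches), length(x$unmatched_observed),
              length(x$unmatched_expected),
              if (x$identical_within_tolerance) "match" else "MISMATCH"))
  invisible(x)
}
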