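# Core data model: DNA molecules with topology and typed features.
#
# Coordinates are 0-based half-open internally ([start, end)); user-facing
# reports convert to 1-based inclusive. Circular molecules are stored as a
# linearized sequence plus a topology flag; every interval operation on a
# circular molecule is rotation-invariant. A wrap-around feature on a
# circular molecule is represented with start > end, meaning
# [start, L) + [0, end).

#' Construct a DNA molecule
#'
#' @param id Character scalar identifier.
#' @param seq DNA sequence over \code{A,C,G,T,N} (case-insensitive; stored
#'   uppercase).
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param features A feature data frame as built by \code{\link{feature}} /
#'   \code{\link{feature_table}}, or \code{NULL}.
#' @return An object of class \code{dna_molecule}.
#' @export
#' @examples
#' m <- dna_molecule("oligo", "ACGTACGT")
#' mol_len(m)
dna_molecule <- function(id, seq, topology = c("linear", "circular"),
                         features = NULL) {
  topology <- match.arg(topology)
  seq <- toupper(as.character(seq))
  if (is.null(features)) features <- feature_table()
  mol <- structure(
    list(id = as.character(id), seq = seq, topology = topology,
         features = features),
    class = "dna_molecule"
  )
  validate_dna_molecule(mol)
  mol
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule> %s: %s, %d bp, %d feature(s)\n",
              x$id, x$topology, mol_len(x), nrow(x$features)))
  invisible(x)
}

#' Empty/typed feature table
#'
#' @param kind,start,end,strand,label Parallel vectors describing features;
#'   all may be empty. \code{start}/\code{end} are 0-based half-open.
#' @return A data frame with columns kind, start, end, strand, label.
#' @export
feature_table <- function(kind = character(), start = integer(),
                          end = integer(), strand = character(),
                          label = character()) {
  data.frame(kind = as.character(kind), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             label = as.character(label), stringsAsFactors = FALSE)
}

#' Single feature row
#'
#' @inheritParams feature_table
#' @export
feature <- function(kind, start, end, strand = "+", label = "") {
  feature_table(kind, start, end, strand, label)
}

#' Append features to a molecule
#'
#' @param mol A \code{dna_molecule}.
#' @param feats Feature data frame.
#' @return The molecule with features appended (re-validated).
#' @export
add_features <- function(mol, feats) {
  mol$features <- rbind(mol$features, feats)
  validate_dna_molecule(mol)
  mol
}

#' Molecule length in bases
#' @param mol A \code{dna_molecule}.
#' @export
mol_len <- function(mol) nchar(mol$seq)

#' Features of a given kind
#' @param mol A \code{dna_molecule}.
#' @param kind Feature kind to select.
#' @return Feature data frame subset, ordered by start.
#' @export
features_of <- function(mol, kind) {
  f <- mol$features[mol$features$kind == kind, , drop = FALSE]
  f[order(f$start), , drop = FALSE]
}

validate_dna_molecule <- function(mol) {
  if (!nzchar(mol$seq)) stop("sequence must be non-empty", call. = FALSE)
  if (grepl("[^ACGTN]", mol$seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  f <- mol$features
  if (nrow(f)) {
    L <- mol_len(mol)
    bad_kind <- setdiff(unique(f$kind), FEATURE_KINDS)
    if (length(bad_kind)) {
      stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "),
           call. = FALSE)
    }
    if (any(!f$strand %in% c("+", "-"))) {
      stop("feature strand must be '+' or '-'", call. = FALSE)
    }
    if (mol$topology == "linear") {
      if (any(f$start < 0L | f$end > L | f$start >= f$end)) {
        stop("linear feature intervals must satisfy 0 <= start < end <= length",
             call. = FALSE)
      }
    } else {
      if (any(f$start < 0L | f$start >= L | f$end <= 0L | f$end > L)) {
        stop("circular feature coordinates out of range", call. = FALSE)
      }
    }
    site <- f$kind %in% c("loxP", "FRT")
    if (any(site)) {
      lens <- feature_lengths(f[site, , drop = FALSE], L)
      if (any(lens != 34L)) {
        stop("loxP and FRT features must be exactly 34 bases long",
             call. = FALSE)
      }
    }
  }
  invisible(mol)
}

# Feature lengths, honouring wrap-around (start > end) on circular molecules.
feature_lengths <- function(f, L) {
  ifelse(f$end > f$start, f$end - f$start, L - f$start + f$end)
}

#' Reverse complement of a DNA string
#' @param s Character scalar DNA sequence.
#' @export
revcomp_seq <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Reverse complement a molecule, remapping features
#'
#' Feature intervals are mirrored (\code{[s, e)} becomes \code{[L-e, L-s)})
#' and strands flipped; feature lengths are preserved.
#'
#' @param mol A \code{dna_molecule}.
#' @export
reverse_complement <- function(mol) {
  L <- mol_len(mol)
  f <- mol$features
  if (nrow(f)) {
    new_start <- L - f$end
    new_end <- L - f$start
    if (mol$topology == "circular") {
      new_start <- new_start %% L
      new_end <- ((new_end - 1L) %% L) + 1L
    }
    f$start <- as.integer(new_start)
    f$end <- as.integer(new_end)
    f$strand <- ifelse(f$strand == "+", "-", "+")
  }
  out <- mol
  out$seq <- revcomp_seq(mol$seq)
  out$features <- f
  validate_dna_molecule(out)
  out
}

#' Rotate the origin of a circular molecule
#'
#' Moves the sequence origin to position \code{k} (0-based). All interval
#' operations in the package are invariant under this rotation.
#'
#' @param mol A circular \code{dna_molecule}.
#' @param k New origin, 0-based position in the current linearization.
#' @export
rotate_molecule <- function(mol, k) {
  if (mol$topology != "circular") stop("can only rotate circular molecules",
                                       call. = FALSE)
  L <- mol_len(mol)
  k <- as.integer(k %% L)
  if (k == 0L) return(mol)
  out <- mol
  out$seq <- paste0(substr(mol$seq, k + 1L, L), substr(mol$seq, 1L, k))
  f <- mol$features
  if (nrow(f)) {
    f$start <- as.integer((f$start - k) %% L)
    f$end <- as.integer(((f$end - k - 1L) %% L) + 1L)
  }
  out$features <- f
  out
}

# 0-based half-open subsequence with circular wrap. `end >= start`; `end`
# may exceed the sequence length (the span then wraps past the origin).
subseq_circular <- function(s, start, end) {
  L <- nchar(s)
  n <- end - start
  if (n < 0L || n > L) stop("invalid circular span", call. = FALSE)
  if (n == 0L) return("")
  start <- start %% L
  if (start + n <= L) {
    substr(s, start + 1L, start + n)
  } else {
    paste0(substr(s, start + 1L, L), substr(s, 1L, start + n - L))
  }
}

# All 0-based start positions of `pattern` in molecule `mol` on the stored
# (+) strand, circular-aware (matches may span the origin).
find_pattern <- function(mol, pattern) {
  s <- mol$seq
  if (mol$topology == "circular" && nchar(pattern) > 1L) {
    s <- paste0(s, substr(mol$seq, 1L, min(nchar(pattern) - 1L, nchar(mol$seq))))
  }
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(s)
  )) - 1L
  hits[hits < mol_len(mol)]
}

# Pattern positions on both strands: list(fwd = starts, rev = starts of the
# reverse complement on the stored strand).
find_pattern_both <- function(mol, pattern) {
  list(fwd = find_pattern(mol, pattern),
       rev = find_pattern(mol, revcomp_seq(pattern)))
}

#' Sequence identity test, rotation-aware for circular molecules
#'
#' Two circular double-stranded molecules are the same molecule when one
#' stored sequence is a rotation of the other or of its reverse complement
#' (a circle has neither a fixed origin nor a canonical strand). Linear
#' molecules must match exactly.
#'
#' @param a,b \code{dna_molecule} objects.
#' @return Logical scalar.
#' @export
same_sequence <- function(a, b) {
  if (mol_len(a) != mol_len(b)) return(FALSE)
  if (a$topology != b$topology) return(FALSE)
  if (a$topology == "circular") {
    dbl <- paste0(a$seq, a$seq)
    grepl(b$seq, dbl, fixed = TRUE) ||
      grepl(revcomp_seq(b$seq), dbl, fixed = TRUE)
  } else {
    identical(a$seq, b$seq)
  }
}

# Convert internal 0-based half-open to 1-based inclusive for reports.
to_onebased <- function(start, end) list(start = start + 1L, end = end)
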