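# Allele quality control: does the designed/simulated allele have the
# intended structure, and does Cre-mediated excision of the critical
# exon(s) frameshift the remaining coding sequence into a premature stop
# (a functional null)?
#
# Splicing model: simple exon concatenation in gene order (no alternative
# or cryptic splicing). Translation uses the standard nuclear code. A
# design whose removed CDS length is a multiple of 3 is reported as a
# warning, not an error: the tool reports, the designer decides.

#' Check that removal of the critical exon(s) yields a frameshifted null
#'
#' @param gene A \code{gene_model}.
#' @param removed_exons Gene-order exon indices removed by Cre. None may
#'   be the first or last coding exon (the splice model needs flanking
#'   exons).
#' @param locus Optional locus \code{dna_molecule}; when supplied, the
#'   post-excision CDS is spliced and translated and the first premature
#'   stop codon reported.
#' @return List of class \code{allele_report} fragment:
#'   \code{removed_cds_len}, \code{frameshift}, and (with sequence)
#'   \code{first_premature_stop} (1-based codon index in the post-excision
#'   CDS, or \code{NA}).
#' @export
check_conditional_null <- function(gene, removed_exons, locus = NULL) {
  removed_exons <- as.integer(removed_exons)
  if (length(removed_exons) == 0L) {
    stop("removed_exons must be non-empty", call. = FALSE)
  }
  rows <- exon_row(gene, removed_exons)  # validates indices
  coding_rows <- sort(unique(gene$cds_exon))
  if (!all(rows %in% coding_rows)) {
    stop("removed exon carries no CDS; its removal cannot frameshift",
         call. = FALSE)
  }
  first_last <- range(coding_rows)
  if (any(rows %in% first_last)) {
    stop("cannot remove the first or last coding exon: the splice model ",
         "needs intact flanking coding exons", call. = FALSE)
  }
  removed_cds_len <- cds_len_in_exons(gene, removed_exons)
  frameshift <- (removed_cds_len %% 3L) != 0L
  if (!frameshift) {
    warning("removed CDS length ", removed_cds_len,
            " is a multiple of 3: excision preserves the reading frame ",
            "(design warning)")
  }
  out <- list(removed_exons = removed_exons,
              removed_cds_len = removed_cds_len,
              frameshift = frameshift,
              first_premature_stop = NA_integer_)
  if (!is.null(locus)) {
    full <- spliced_cds_seq(gene, locus$seq)
    post <- spliced_cds_seq(gene, locus$seq, drop_exons = removed_exons)
    n_cod <- nchar(post) %/% 3L
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(post, 1L, n_cod * 3L)),
      if.fuzzy.codon = "X"
    ))
    stops <- unlist(gregexpr("*", aa, fixed = TRUE))
    stops <- stops[stops > 0L]
    natural_len <- nchar(full) %/% 3L  # includes the natural stop codon
    premature <- stops[stops < natural_len]
    out$first_premature_stop <- if (length(premature)) premature[1] else
      NA_integer_
  }
  class(out) <- "allele_report"
  out
}

#' Verify the structure of a simulated or loaded targeting vector
#'
#' Counts loxP/FRT features, measures the ES-cell homology arms (genomic
#' sequence upstream of the first loxP and downstream of the last loxP
#' within the retrieved region), flags arms outside the acceptable range,
#' and confirms that the critical exon lies strictly between the two loxP
#' sites.
#'
#' @param vector \code{dna_molecule} produced by \code{\link{gap_repair}}
#'   (or loaded from GenBank with its features).
#' @param gene Optional \code{gene_model} (to name the critical exon in
#'   the report).
#' @param params \code{\link{design_parameters}} (for \code{es_arm_range}).
#' @return List of class \code{allele_report}: \code{lox_count},
#'   \code{frt_count}, \code{arm5_len}, \code{arm3_len},
#'   \code{es_arm_in_range}, \code{critical_exon_floxed}.
#' @export
verify_allele_structure <- function(vector, gene = NULL,
                                    params = design_parameters()) {
  if (nrow(features_of(vector, "loxP")) == 0L) {
    stop("vector carries no loxP features", call. = FALSE)
  }
  # retrieved genomic region is bounded by the labelled retrieval junction
  # arms; re-origin the circle there so the region is contiguous even after
  # downstream recombination steps moved the origin
  sel <- grepl("retrieval_arm_genomic", vector$features$label)
  if (sum(sel) == 2L && vector$topology == "circular") {
    a5 <- vector$features[vector$features$label == "retrieval_arm_genomic_5p", ]
    if (nrow(a5) == 1L) vector <- rotate_molecule(vector, a5$start[1])
    sel <- grepl("retrieval_arm_genomic", vector$features$label)
  }
  lox <- features_of(vector, "loxP")
  frt <- features_of(vector, "FRT")
  arms <- vector$features[sel, , drop = FALSE]
  if (nrow(arms) == 2L) {
    ret_lo <- min(arms$start)
    ret_hi <- max(arms$end)
  } else {
    ret_lo <- 0L
    ret_hi <- mol_len(vector)
  }
  lox_in <- lox[lox$start >= ret_lo & lox$end <= ret_hi, , drop = FALSE]
  arm5 <- if (nrow(lox_in)) min(lox_in$start) - ret_lo else NA_integer_
  arm3 <- if (nrow(lox_in)) ret_hi - max(lox_in$end) else NA_integer_
  rng <- params$es_arm_range
  in_range <- if (is.na(arm5) || is.na(arm3)) NA else
    arm5 >= rng[1] && arm5 <= rng[2] && arm3 >= rng[1] && arm3 <= rng[2]
  if (isFALSE(in_range)) {
    warning("ES homology arms (", arm5, ", ", arm3,
            " bases) fall outside the recommended range [", rng[1], ", ",
            rng[2], "]")
  }
  floxed <- NA
  if (nrow(lox_in) >= 2L) {
    ex <- features_of(vector, "exon")
    crit_lab <- if (!is.null(gene) && length(gene$critical_exons)) {
      paste0(gene$gene_id, ":exon", gene$critical_exons)
    } else NULL
    crit <- if (!is.null(crit_lab)) {
      ex[ex$label %in% crit_lab, , drop = FALSE]
    } else ex
    if (nrow(crit)) {
      lo <- min(lox_in$end)
      hi <- max(lox_in$start)
      floxed <- all(crit$start >= lo & crit$end <= hi)
    }
  }
  structure(list(lox_count = nrow(lox), frt_count = nrow(frt),
                 arm5_len = as.integer(arm5), arm3_len = as.integer(arm3),
                 es_arm_in_range = in_range,
                 critical_exon_floxed = floxed),
            class = "allele_report")
}

#' @export
print.allele_report <- function(x, ...) {
  cat("<allele_report>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
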