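# Lagging-strand logic for BAC co-targeting oligos.
#
# pBACe3.6-backbone BACs replicate unidirectionally from OriS, with the
# fork moving in the direction of Sp6 transcription (Sp6 toward T7). On the
# genome browser the insert orientation is drawn as an arrow from T7 toward
# Sp6; the lagging strand therefore runs 5'->3' in the arrow direction. The
# operational rule: a gene transcribed in the same direction as the
# T7->Sp6 arrow has its coding strand as the lagging strand; a gene
# transcribed against the arrow has its template strand as the lagging
# strand. Strand choice affects in-vivo oligo efficiency only; the in
# silico recombineering product is identical for either strand.

#' Construct a BAC clone
#'
#' A mock clone: genomic insert (stored genome-forward) plus a backbone
#' stub carrying Sp6/T7 ends and the OriS origin, assembled as a circular
#' molecule. \code{insert_orientation} records the direction of the
#' genome-forward axis expressed on the T7/Sp6 axis (the browser arrow
#' convention): \code{"T7_to_Sp6"} means genome-forward runs from the T7
#' end toward the Sp6 end.
#'
#' @param clone_id Character identifier.
#' @param insert A linear \code{dna_molecule}, genome-forward orientation.
#' @param insert_orientation \code{"T7_to_Sp6"} or \code{"Sp6_to_T7"}.
#' @param backbone A linear backbone stub (see
#'   \code{\link{make_mock_backbone}}); its features must include the T7
#'   and Sp6 promoter ends and the origin.
#' @param insert_interval Optional genomic interval (0-based half-open,
#'   list or length-2 vector) of the insert on its source chromosome; used
#'   to check that a gene lies within the insert. Defaults to the whole
#'   insert.
#' @return An object of class \code{bac_clone}; element \code{molecule}
#'   holds the assembled circular clone.
#' @export
bac_clone <- function(clone_id, insert,
                      insert_orientation = c("T7_to_Sp6", "Sp6_to_T7"),
                      backbone, insert_interval = NULL) {
  insert_orientation <- match.arg(insert_orientation)
  if (is.null(insert_interval)) insert_interval <- c(0L, mol_len(insert))
  insert_interval <- as.integer(unlist(insert_interval))
  if (insert_interval[2] <= insert_interval[1]) {
    stop("insert interval must be non-empty", call. = FALSE)
  }
  # Assemble backbone + insert so that walking from the T7 end toward the
  # Sp6 end reads the insert in the stated orientation. The backbone stub
  # is laid out [Sp6 end ... OriS ... T7 end]; the insert follows the T7
  # end, and the circle closes back onto the Sp6 end.
  oriented <- if (insert_orientation == "T7_to_Sp6") insert else
    reverse_complement(insert)
  bl <- mol_len(backbone)
  feats <- oriented$features
  if (nrow(feats)) {
    feats$start <- feats$start + bl
    feats$end <- feats$end + bl
  }
  assembled <- dna_molecule(
    clone_id, paste0(backbone$seq, oriented$seq), "circular",
    rbind(backbone$features, feats)
  )
  structure(
    list(clone_id = clone_id, insert = insert,
         insert_orientation = insert_orientation, backbone = backbone,
         insert_interval = insert_interval, molecule = assembled),
    class = "bac_clone"
  )
}

#' @export
print.bac_clone <- function(x, ...) {
  cat(sprintf("<bac_clone> %s: %d bp circular, insert %d bp (%s)\n",
              x$clone_id, mol_len(x$molecule), mol_len(x$insert),
              x$insert_orientation))
  invisible(x)
}

#' Infer which gene strand is the lagging strand for a BAC clone
#'
#' Applies the arrow rule: when the gene is transcribed in the same
#' direction as the T7->Sp6 arrow (equivalently, the T7 promoter), the
#' lagging strand equals the coding strand; otherwise it equals the
#' template strand. The returned rationale string records both inputs and
#' the rule branch taken.
#'
#' @param bac A \code{bac_clone}.
#' @param gene A \code{gene_model} whose coordinates lie on the genomic
#'   axis of the BAC insert.
#' @return An object of class \code{strand_call} with fields
#'   \code{lagging_equals} (\code{"coding_strand"} or
#'   \code{"template_strand"}) and \code{rationale}.
#' @export
infer_lagging_strand <- function(bac, gene) {
  span <- c(min(gene$exons$start), max(gene$exons$end))
  if (span[1] < bac$insert_interval[1] || span[2] > bac$insert_interval[2]) {
    stop("gene [", span[1], ",", span[2], ") lies outside the BAC insert [",
         bac$insert_interval[1], ",", bac$insert_interval[2], ")",
         call. = FALSE)
  }
  gene_forward <- gene$strand == "+"
  arrow_forward <- bac$insert_orientation == "T7_to_Sp6"
  same <- gene_forward == arrow_forward
  lagging <- if (same) "coding_strand" else "template_strand"
  rationale <- sprintf(
    paste0("gene %s transcribed on '%s' (genome-forward axis); insert ",
           "orientation %s so the T7->Sp6 arrow is genome-%s; replication ",
           "runs Sp6 toward T7, lagging strand runs with the arrow; gene ",
           "%s the arrow => lagging strand = %s"),
    gene$gene_id, gene$strand, bac$insert_orientation,
    if (arrow_forward) "forward" else "reverse",
    if (same) "matches" else "opposes", lagging
  )
  structure(list(lagging_equals = lagging, rationale = rationale),
            class = "strand_call")
}

#' @export
print.strand_call <- function(x, ...) {
  cat(sprintf("<strand_call> lagging strand = %s\n  %s\n",
              x$lagging_equals, x$rationale))
  invisible(x)
}

#' Orient a co-targeting oligo to the selected strand
#'
#' Oligos are designed on the genome-forward strand of the locus. The
#' lagging-strand version is the coding-strand sequence when the call is
#' \code{coding_strand}, and the template-strand (reverse complement of
#' the coding strand) sequence otherwise. An attribute records the choice;
#' by design, \code{lagging == revcomp(leading)} for every oligo.
#'
#' @param oligo The designed oligo (\code{dna_molecule},
#'   genome-forward strand).
#' @param call A \code{strand_call}.
#' @param gene The \code{gene_model} the oligo was designed against.
#' @param choice Emit the \code{"lagging"} (default) or \code{"leading"}
#'   strand version.
#' @return The oriented oligo, with attributes \code{strand_choice} and
#'   \code{oligo_strand} (\code{"coding"}/\code{"template"}).
#' @export
orient_oligo <- function(oligo, call, gene, choice = c("lagging", "leading")) {
  choice <- match.arg(choice)
  want_coding <- (call$lagging_equals == "coding_strand") == (choice == "lagging")
  # the oligo records which genomic strand it was designed on; that is the
  # coding strand when it matches the gene strand
  designed_on <- attr(oligo, "designed_on")
  if (is.null(designed_on)) designed_on <- "+"
  designed_is_coding <- designed_on == gene$strand
  out <- if (want_coding == designed_is_coding) oligo else
    reverse_complement(oligo)
  attr(out, "strand_choice") <- choice
  attr(out, "oligo_strand") <- if (want_coding) "coding" else "template"
  out
}
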