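# End-to-end workflow: cassette prep by recombineering in the carrier
# plasmid, release digest, BAC co-targeting (double-stranded cassette +
# single-stranded loxP oligo), gap-repair retrieval into the linearized
# retrieval vector, then the downstream Flp and Cre products.

pick_product <- function(products, marker_label) {
  has <- vapply(products, function(m) any(grepl(marker_label,
                                                m$features$label)),
                logical(1))
  if (sum(has) != 1L) {
    stop("expected exactly one product carrying '", marker_label, "'",
         call. = FALSE)
  }
  products[[which(has)]]
}

#' Run the complete in-silico CKO construction workflow
#'
#' Steps: (1) insert the neo fragment into the carrier plasmid by
#' double-stranded recombineering (via its Pgk1/BGHpA homologies);
#' (2) release the size-shifted cassette by digestion; (3) co-target the
#' BAC with the released cassette and the loxP oligo; (4) linearize the
#' retrieval vector and retrieve the modified interval by gap repair,
#' giving the final CKO vector; (5) Flp out the neo marker (post-Flp
#' allele analog); (6) Cre out the floxed critical exon (post-Cre / KO
#' allele analog).
#'
#' @param fx An end-to-end fixture from \code{\link{make_end_to_end_fixture}},
#'   or any list with the same elements (\code{bundle}, \code{bac},
#'   \code{puc_carrier}, \code{neo_fragment}, \code{retrieval_vector},
#'   \code{params}).
#' @param use_oriented_oligo Use the lagging-strand oriented oligo
#'   (default) rather than the designed genome-forward version; the
#'   product is identical either way.
#' @return Named list: \code{prep_plasmid}, \code{released_cassette},
#'   \code{cotargeted_bac}, \code{cko_vector}, \code{post_flp},
#'   \code{post_flp_excised}, \code{post_cre}, \code{post_cre_excised},
#'   \code{mixed_prep_bands}, \code{trace}.
#' @export
run_cko_pipeline <- function(fx, use_oriented_oligo = TRUE) {
  params <- fx$params
  # (1) cassette prep in the carrier plasmid
  prep <- recombineer_ds(fx$puc_carrier, fx$neo_fragment,
                         min_arm = params$min_arm)
  # (2) release digest; a real miniprep is a parent/recombined mixture, so
  # the gel shows the union of both digests
  release_enz <- unique(c(params$cassette_site_enzyme_5,
                          params$cassette_site_enzyme_3))
  mixed_bands <- sort(unique(c(digest(fx$puc_carrier, release_enz)$lengths,
                               digest(prep, release_enz)$lengths)))
  released <- release_cassette(prep, release_enz[1])
  # (3) co-targeting: order of the two events does not change the product
  oligo <- if (use_oriented_oligo) fx$bundle$lox_oligo else
    fx$bundle$lox_oligo_designed
  cot <- recombineer_ds(fx$bac$molecule, released, min_arm = params$min_arm)
  cot <- recombineer_ss(cot, oligo, min_arm = params$min_arm)
  # (4) retrieval by gap repair
  lin <- linearize(fx$retrieval_vector, params$retrieval_linearization_enzyme)
  cko <- gap_repair(cot, lin, min_arm = params$min_arm)
  # (5) Flp removes the neo marker; the backbone-side circle is the allele
  flp <- site_specific_recombine(cko, "FRT")
  post_flp <- pick_product(flp, "HSV_TK")
  # (6) Cre removes the floxed critical exon (and the residual FRT)
  cre <- site_specific_recombine(post_flp, "loxP")
  post_cre <- pick_product(cre, "HSV_TK")
  list(
    prep_plasmid = prep, released_cassette = released,
    cotargeted_bac = cot, cko_vector = cko,
    post_flp = post_flp,
    post_flp_excised = setdiff_product(flp, post_flp),
    post_cre = post_cre,
    post_cre_excised = setdiff_product(cre, post_cre),
    mixed_prep_bands = mixed_bands,
    trace = list(prep = attr(prep, "trace"),
                 cotarget = attr(cot, "trace"),
                 gap_repair = attr(cko, "trace"))
  )
}

setdiff_product <- function(products, chosen) {
  other <- products[!vapply(products, identical, logical(1), chosen)]
  other[[1]]
}
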