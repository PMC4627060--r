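# Gene model: ordered exons with CDS sub-intervals, strand, and the
# user-designated critical exon(s). Coordinates are 0-based half-open on
# the locus (genome-forward axis); exon indices are 1-based in gene order
# (exon 1 is the 5'-most exon in transcription orientation).

#' Construct a gene model
#'
#' @param gene_id Character identifier.
#' @param strand \code{"+"} or \code{"-"} (transcription direction on the
#'   genome-forward axis of the locus).
#' @param exons Data frame with integer columns \code{start}, \code{end}
#'   (0-based half-open, genome-forward coordinates). Must be
#'   non-overlapping.
#' @param cds Data frame like \code{exons}; every CDS interval must lie
#'   within exactly one exon.
#' @param critical_exons Integer vector of exon indices (gene order).
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, strand, exons, cds,
                       critical_exons = integer()) {
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand, call. = FALSE)
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  rownames(exons) <- rownames(cds) <- NULL
  if (nrow(exons) == 0L) stop("gene model needs at least one exon", call. = FALSE)
  if (any(exons$start >= exons$end) || (nrow(cds) && any(cds$start >= cds$end))) {
    stop("intervals must satisfy start < end", call. = FALSE)
  }
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exons must be non-overlapping", call. = FALSE)
  }
  # every CDS interval inside exactly one exon
  if (nrow(cds)) {
    host <- vapply(seq_len(nrow(cds)), function(i) {
      hits <- which(exons$start <= cds$start[i] & exons$end >= cds$end[i])
      if (length(hits) != 1L) {
        stop("CDS interval [", cds$start[i], ",", cds$end[i],
             ") does not lie within exactly one exon", call. = FALSE)
      }
      hits
    }, integer(1))
  } else {
    host <- integer()
  }
  n <- nrow(exons)
  critical_exons <- as.integer(critical_exons)
  if (length(critical_exons) && any(critical_exons < 1L | critical_exons > n)) {
    stop("critical exon index out of range", call. = FALSE)
  }
  structure(
    list(gene_id = as.character(gene_id), strand = strand, exons = exons,
         cds = cds, cds_exon = as.integer(host),
         critical_exons = critical_exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s): %d exon(s), %d CDS segment(s), critical: %s\n",
              x$gene_id, x$strand, nrow(x$exons), nrow(x$cds),
              if (length(x$critical_exons)) paste(x$critical_exons, collapse = ",")
              else "none"))
  invisible(x)
}

#' Number of exons
#' @param gene A \code{gene_model}.
#' @export
n_exons <- function(gene) nrow(gene$exons)

# Map a gene-order exon index (1 = 5'-most in transcription orientation)
# to the row of the genomic-order exon table.
exon_row <- function(gene, exon_index) {
  n <- n_exons(gene)
  if (any(exon_index < 1L | exon_index > n)) {
    stop("exon index out of range", call. = FALSE)
  }
  if (gene$strand == "+") exon_index else n - exon_index + 1L
}

#' Genomic interval of an exon, by gene-order index
#' @param gene A \code{gene_model}.
#' @param exon_index 1-based exon index in gene (transcription) order.
#' @return List with \code{start}, \code{end} (0-based half-open).
#' @export
exon_interval <- function(gene, exon_index) {
  r <- exon_row(gene, exon_index)
  list(start = gene$exons$start[r], end = gene$exons$end[r])
}

#' Total CDS bases within given exons
#' @param gene A \code{gene_model}.
#' @param exon_index Gene-order exon indices.
#' @export
cds_len_in_exons <- function(gene, exon_index) {
  rows <- exon_row(gene, exon_index)
  sum(gene$cds$end[gene$cds_exon %in% rows] - gene$cds$start[gene$cds_exon %in% rows])
}

# Spliced CDS sequence (5'->3' in gene orientation) from a locus sequence,
# optionally excluding CDS segments hosted by the given exons (gene-order
# indices). Used by the conditional-null check.
spliced_cds_seq <- function(gene, locus_seq, drop_exons = integer()) {
  keep <- rep(TRUE, nrow(gene$cds))
  if (length(drop_exons)) {
    keep <- !(gene$cds_exon %in% exon_row(gene, drop_exons))
  }
  segs <- gene$cds[keep, , drop = FALSE]
  s <- paste0(vapply(seq_len(nrow(segs)), function(i) {
    substr(locus_seq, segs$start[i] + 1L, segs$end[i])
  }, character(1)), collapse = "")
  if (gene$strand == "-") s <- revcomp_seq(s)
  s
}

# exon/CDS features (genome-forward) for attaching to a locus molecule, so
# gene structure travels with the sequence through every simulated step.
gene_features <- function(gene) {
  n <- n_exons(gene)
  idx_in_gene_order <- if (gene$strand == "+") seq_len(n) else rev(seq_len(n))
  rbind(
    feature_table("exon", gene$exons$start, gene$exons$end,
                  rep(gene$strand, n),
                  paste0(gene$gene_id, ":exon", idx_in_gene_order)),
    if (nrow(gene$cds)) {
      feature_table("CDS", gene$cds$start, gene$cds$end,
                    rep(gene$strand, nrow(gene$cds)),
                    paste0(gene$gene_id, ":cds"))
    }
  )
}
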