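# Readers and writers: FASTA locus + BED6/BED12/GFF3 gene annotation in,
# FASTA/GenBank constructs and YAML/JSON configs out. Standard-format
# parsing is delegated to Biostrings / rtracklayer; coordinates are
# converted to the internal 0-based half-open convention at the boundary.

#' Load a genomic locus with its gene model
#'
#' Reads a single-record FASTA and a BED6/BED12 or minimal GFF3 annotation
#' describing the exon/CDS structure of one gene. For BED12, blocks are the
#' exons and the thick interval the CDS. For BED6, each line is one exon
#' and the gene is taken as fully coding. For GFF3, \code{exon} and
#' \code{CDS} lines are used.
#'
#' @param fasta_path Path to a FASTA file holding exactly one record.
#' @param annotation_path Path to the gene annotation (.bed / .gff / .gff3).
#' @param critical_exons Integer vector of critical exon indices
#'   (gene order), attached to the gene model.
#' @return List with elements \code{molecule} (a \code{dna_molecule}, with
#'   exon/CDS features attached) and \code{gene} (a \code{gene_model}).
#' @export
load_locus <- function(fasta_path, annotation_path,
                       critical_exons = integer()) {
  recs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(recs) != 1L) {
    stop("locus FASTA must hold exactly one record, found ", length(recs),
         call. = FALSE)
  }
  id <- strsplit(names(recs)[1], "[[:space:]]+")[[1]][1]
  mol <- dna_molecule(id, as.character(recs[[1]]), "linear")

  gene <- read_gene_annotation(annotation_path, critical_exons)
  mol <- add_features(mol, gene_features(gene))
  list(molecule = mol, gene = gene)
}

read_gene_annotation <- function(path, critical_exons = integer()) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  gr <- if (is_gff) {
    rtracklayer::import(path, format = "gff3")
  } else {
    rtracklayer::import(path, format = "bed")
  }
  strand <- unique(as.character(GenomicRanges::strand(gr)))
  if (length(strand) != 1L || !strand %in% c("+", "-")) {
    stop("gene annotation must carry a single known strand (+/-)",
         call. = FALSE)
  }
  if (is_gff) {
    types <- tolower(as.character(gr$type))
    ex <- gr[types == "exon"]
    cd <- gr[types == "cds"]
    if (length(ex) == 0L) stop("GFF3 annotation has no exon lines", call. = FALSE)
    gene_id <- if (!is.null(ex$Parent) && length(unlist(ex$Parent))) {
      as.character(unlist(ex$Parent))[1]
    } else if (!is.null(ex$ID)) as.character(ex$ID)[1] else "gene"
    exons <- granges_to_iv(ex)
    cds <- granges_to_iv(cd)
  } else if (!is.null(gr$blocks) && length(gr) == 1L) {
    # BED12: one record; blocks = exons (relative), thick = CDS region
    off <- GenomicRanges::start(gr) - 1L
    bl <- gr$blocks[[1]]
    exons <- data.frame(start = BiocGenerics::start(bl) - 1L + off,
                        end = BiocGenerics::end(bl) + off)
    th <- gr$thick
    cds_lo <- GenomicRanges::start(th) - 1L
    cds_hi <- GenomicRanges::end(th)
    cds <- data.frame(
      start = pmax(exons$start, cds_lo),
      end = pmin(exons$end, cds_hi)
    )
    cds <- cds[cds$start < cds$end, , drop = FALSE]
    gene_id <- if (!is.null(gr$name)) as.character(gr$name) else "gene"
  } else {
    # BED6: one line per exon, fully coding
    exons <- granges_to_iv(gr)
    cds <- exons
    gene_id <- if (!is.null(gr$name)) as.character(gr$name)[1] else "gene"
  }
  gene_model(gene_id, strand, exons, cds, critical_exons)
}

granges_to_iv <- function(gr) {
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Write a construct to FASTA or GenBank
#'
#' GenBank output carries topology and all features (loxP/FRT as
#' \code{misc_recomb}, primer sites as \code{primer_bind}); FASTA output is
#' sequence only.
#'
#' @param mol A \code{dna_molecule}.
#' @param path Output path.
#' @param format \code{"fasta"} or \code{"genbank"}.
#' @return Invisibly, \code{path}.
#' @export
write_construct <- function(mol, path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "fasta") {
    dir <- dirname(path)
    if (!dir.exists(dir) || file.access(dir, 2L) != 0L) {
      stop("cannot write to ", path, call. = FALSE)
    }
    ss <- Biostrings::DNAStringSet(mol$seq)
    names(ss) <- mol$id
    Biostrings::writeXStringSet(ss, path)
  } else {
    write_genbank(mol, path)
  }
  invisible(path)
}

#' Read a FASTA record as a molecule
#' @param path FASTA path (single record).
#' @param topology Molecule topology.
#' @export
read_fasta_molecule <- function(path, topology = "linear") {
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) != 1L) stop("expected a single FASTA record", call. = FALSE)
  dna_molecule(strsplit(names(recs)[1], "[[:space:]]+")[[1]][1],
               as.character(recs[[1]]), topology)
}

#' Read a design configuration (YAML or JSON)
#'
#' The config carries the design coordinates, BAC clone metadata and any
#' parameter overrides; see the packaged CLI for the expected keys.
#'
#' @param path Config path (.yaml/.yml/.json).
#' @return Named list.
#' @export
read_design_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# One-line BED12 for a gene model (used by the fixture writer).
write_gene_bed12 <- function(gene, chrom, path) {
  ex <- gene$exons
  cds <- gene$cds
  chrom_start <- min(ex$start)
  thick <- if (nrow(cds)) c(min(cds$start), max(cds$end)) else
    c(chrom_start, chrom_start)
  line <- paste(
    chrom, chrom_start, max(ex$end), gene$gene_id, 0L, gene$strand,
    thick[1], thick[2], "0", nrow(ex),
    paste0(paste(ex$end - ex$start, collapse = ","), ","),
    paste0(paste(ex$start - chrom_start, collapse = ","), ","),
    sep = "\t"
  )
  writeLines(line, path)
  invisible(path)
}
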