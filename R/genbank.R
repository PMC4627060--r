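# Minimal GenBank flat-file writer/parser for designed constructs.
#
# Covers exactly what the toolkit needs: LOCUS topology, a feature table
# with simple, complement() and origin-spanning join() locations, and the
# ORIGIN sequence block. Feature kind is stored losslessly in a
# /note="kind=..." qualifier; the display key follows convention
# (misc_recomb for loxP/FRT, primer_bind for primer sites).

gb_feature_key <- function(kind) {
  switch(kind,
    loxP = "misc_recomb", FRT = "misc_recomb",
    primer_site = "primer_bind",
    exon = "exon", CDS = "CDS",
    origin = "rep_origin",
    "misc_feature"
  )
}

gb_location <- function(start, end, strand, L, circular) {
  # internal 0-based half-open -> 1-based inclusive GenBank location
  loc <- if (circular && start >= end) {
    sprintf("join(%d..%d,%d..%d)", start + 1L, L, 1L, end)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a molecule as a GenBank flat file
#'
#' @param mol A \code{dna_molecule}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_genbank <- function(mol, path) {
  L <- mol_len(mol)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     substr(mol$id, 1L, 16L), L,
                     mol$topology, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", mol$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- mol$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      key <- gb_feature_key(f$kind[i])
      loc <- gb_location(f$start[i], f$end[i], f$strand[i], L,
                         mol$topology == "circular")
      writeLines(sprintf("     %-15s %s", key, loc), con)
      if (nzchar(f$label[i])) {
        writeLines(sprintf("                     /standard_name=\"%s\"",
                           f$label[i]), con)
      }
      writeLines(sprintf("                     /note=\"kind=%s\"", f$kind[i]),
                 con)
    }
  }
  writeLines("ORIGIN", con)
  sq <- tolower(mol$seq)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(sq, off, min(off + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by this package
#'
#' @param path GenBank file path.
#' @return A \code{dna_molecule}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("not a GenBank file: no LOCUS line", call. = FALSE)
  topology <- if (grepl("circular", locus)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1]][1]

  ori <- grep("^ORIGIN", lines)[1]
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  L <- nchar(sq)

  fstart <- grep("^FEATURES", lines)[1]
  feats <- feature_table()
  if (!is.na(fstart) && ori > fstart + 1L) {
    block <- lines[(fstart + 1L):(ori - 1L)]
    hdr <- grep("^     [^ ]", block)
    for (j in seq_along(hdr)) {
      from <- hdr[j]
      to <- if (j < length(hdr)) hdr[j + 1L] - 1L else length(block)
      toks <- strsplit(trimws(block[from]), "[[:space:]]+")[[1]]
      loc <- toks[2]
      quals <- block[seq(from, to)][-1L]
      kind <- sub(".*kind=([^\"]+)\".*", "\\1",
                  grep("kind=", quals, value = TRUE)[1])
      lab <- grep("/standard_name=", quals, value = TRUE)
      label <- if (length(lab)) sub(".*=\"([^\"]*)\".*", "\\1", lab[1]) else ""
      strand <- if (grepl("^complement", loc)) "-" else "+"
      loc <- gsub("complement\\(|\\)$", "", loc)
      if (grepl("^join", loc)) {
        parts <- strsplit(gsub("join\\(|\\)", "", loc), ",")[[1]]
        a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
        b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
        start <- a[1] - 1L
        end <- b[2]
      } else {
        ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        start <- ab[1] - 1L
        end <- ab[2]
      }
      if (is.na(kind)) kind <- "marker"
      feats <- rbind(feats, feature_table(kind, start, end, strand, label))
    }
  }
  dna_molecule(id, sq, topology, feats)
}
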