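# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths (and Biostrings) so they can serve as
# cross-checks.

# hand-rolled codon table translation, '*' for stops
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3L
  paste(oracle_codon_table[substring(dna, 3L * seq_len(n) - 2L,
                                     3L * seq_len(n))], collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# splice a gene's CDS out of a locus sequence by plain substring
# concatenation, optionally dropping the CDS of some gene-order exons
oracle_spliced_cds <- function(gene, locus_seq, drop_exons = integer()) {
  cds <- gene$cds
  keep <- rep(TRUE, nrow(cds))
  if (length(drop_exons)) {
    n <- nrow(gene$exons)
    rows <- if (gene$strand == "+") drop_exons else n - drop_exons + 1L
    keep <- !(gene$cds_exon %in% rows)
  }
  s <- paste(vapply(which(keep), function(i) {
    substr(locus_seq, cds$start[i] + 1L, cds$end[i])
  }, character(1)), collapse = "")
  if (gene$strand == "-") s <- oracle_revcomp(s)
  s
}

# does excising the given exons truncate the protein? (splice, translate,
# compare protein lengths up to the first stop)
oracle_frameshift_check <- function(gene, locus_seq, removed) {
  full <- oracle_translate(oracle_spliced_cds(gene, locus_seq))
  post <- oracle_translate(oracle_spliced_cds(gene, locus_seq, removed))
  first_stop <- function(p) {
    i <- regexpr("*", p, fixed = TRUE)
    if (i < 0L) nchar(p) + 1L else as.integer(i)
  }
  removed_aa_len <- (nchar(oracle_spliced_cds(gene, locus_seq)) -
                       nchar(oracle_spliced_cds(gene, locus_seq, removed))) / 3
  # in-frame removal: protein shortens by exactly the removed codons and
  # terminates at its natural stop; frameshift: anything else
  !isTRUE(all.equal(first_stop(post), first_stop(full) - removed_aa_len))
}

norm_feats <- function(f) {
  f <- f[order(f$start, f$end, f$kind, f$label), ]
  rownames(f) <- NULL
  f
}

# tiny deterministic random DNA for low-level tests
rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
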