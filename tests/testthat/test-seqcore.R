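# Core molecule model, coordinate arithmetic, and file round-trips.

test_that("molecule construction enforces alphabet and site lengths", {
  expect_error(dna_molecule("x", ""), "non-empty")
  expect_error(dna_molecule("x", "ACGU"), "outside")
  m <- dna_molecule("x", "ACGTNNACGT")
  expect_equal(mol_len(m), 10L)
  expect_error(
    dna_molecule("x", strrep("A", 100),
                 features = feature("loxP", 10, 40)),
    "exactly 34"
  )
  ok <- dna_molecule("x", strrep("A", 100),
                     features = feature("loxP", 10, 44))
  expect_equal(nrow(features_of(ok, "loxP")), 1L)
  expect_error(
    dna_molecule("x", "ACGT", features = feature("nonsense", 0, 2)),
    "unknown feature kind"
  )
})

test_that("reverse complement is an involution that remaps features", {
  s <- rand_dna(60, 11)
  m <- dna_molecule("m", s, features = rbind(
    feature("marker", 0, 4, "+", "a"),
    feature("exon", 20, 35, "-", "b")
  ))
  rc <- reverse_complement(m)
  expect_equal(rc$seq, oracle_revcomp(s))
  # [0,4) on an L-mer maps to [L-4, L) with flipped strand
  a <- rc$features[rc$features$label == "a", ]
  expect_equal(c(a$start, a$end, a$strand), c("56", "60", "-"))
  # lengths preserved
  expect_equal(sort(rc$features$end - rc$features$start),
               sort(m$features$end - m$features$start))
  # involution, including features
  back <- reverse_complement(rc)
  expect_equal(back$seq, m$seq)
  expect_equal(norm_feats(back$features), norm_feats(m$features))
  # palindrome
  expect_equal(reverse_complement(dna_molecule("p", "ACGT"))$seq, "ACGT")
})

test_that("circular interval operations are rotation-invariant", {
  set.seed(7)
  s <- rand_dna(3000, 7)
  m <- dna_molecule("circ", s, "circular",
                    features = feature("marker", 100, 400, "+", "m1"))
  for (k in c(1L, 917L, 2999L)) {
    r <- rotate_molecule(m, k)
    expect_equal(mol_len(r), mol_len(m))
    # digest fragment multiset unchanged
    expect_equal(digest(r, "SpeI")$lengths, digest(m, "SpeI")$lengths)
    # PCR product lengths unchanged (amplicon may span the rotated origin)
    fwd <- substr(s, 151, 170)
    rev <- oracle_revcomp(substr(s, 901, 920))
    expect_equal(pcr(r, fwd, rev), pcr(m, fwd, rev))
    # rotating back restores the original
    expect_equal(rotate_molecule(r, (-k) %% 3000L)$seq, m$seq)
  }
})

test_that("GenBank round-trip preserves sequence, topology and features", {
  oligo <- dna_molecule("oligo1", rand_dna(200, 3), "linear",
                        features = rbind(
                          feature("homology_arm", 0, 83, "+", "flank5"),
                          feature("loxP", 83, 117, "+", "loxP"),
                          feature("homology_arm", 117, 200, "+", "flank3")
                        ))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_construct(oligo, gb, "genbank")
  back <- read_genbank(gb)
  expect_equal(back$seq, oligo$seq)
  expect_equal(back$topology, "linear")
  lox <- features_of(back, "loxP")
  expect_equal(c(lox$start, lox$end), c(83L, 117L))
  expect_equal(norm_feats(back$features), norm_feats(oligo$features))

  circ <- dna_molecule("plasmid1", rand_dna(500, 4), "circular",
                       features = feature("marker", 480, 30, "+", "wrap"))
  gb2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(circ, gb2)
  expect_true(any(grepl("circular", readLines(gb2)[1])))
  back2 <- read_genbank(gb2)
  expect_equal(back2$topology, "circular")
  expect_equal(back2$seq, circ$seq)
  w <- back2$features[back2$features$label == "wrap", ]
  expect_equal(c(w$start, w$end), c(480L, 30L))
})

test_that("locus loading parses BED12/BED6/GFF3 and enforces invariants", {
  dir <- withr::local_tempdir()
  s <- rand_dna(2000, 5)
  fa <- file.path(dir, "locus.fa")
  writeLines(c(">chrT test", s), fa)

  # BED12, + strand, 3 exons, CDS = thick
  bed <- file.path(dir, "gene.bed")
  writeLines(paste("chrT", 100, 1100, "g1", 0, "+", 130, 1050, "0", 3,
                   "200,150,300,", "0,400,700,", sep = "\t"), bed)
  lx <- load_locus(fa, bed)
  expect_equal(n_exons(lx$gene), 3L)
  expect_equal(lx$gene$exons$start, c(100L, 500L, 800L))
  expect_equal(lx$gene$cds$start[1], 130L)
  expect_equal(lx$gene$cds$end[3], 1050L)
  expect_equal(mol_len(lx$molecule), 2000L)
  expect_equal(nrow(features_of(lx$molecule, "exon")), 3L)

  # minus strand: exon 1 must be the 5'-most in gene orientation
  bed_m <- file.path(dir, "gene_minus.bed")
  writeLines(paste("chrT", 100, 1100, "g2", 0, "-", 130, 1050, "0", 3,
                   "200,150,300,", "0,400,700,", sep = "\t"), bed_m)
  gm <- load_locus(fa, bed_m)$gene
  expect_equal(exon_interval(gm, 1)$start, 800L)  # rightmost exon is exon 1
  expect_equal(exon_interval(gm, 3)$start, 100L)

  # multi-record FASTA rejected
  fa2 <- file.path(dir, "two.fa")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa2)
  expect_error(load_locus(fa2, bed), "exactly one record")

  # GFF3 with a CDS extending past its exon rejected
  gff <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               paste("chrT", ".", "exon", 101, 300, ".", "+", ".",
                     "ID=e1;Parent=g3", sep = "\t"),
               paste("chrT", ".", "exon", 501, 800, ".", "+", ".",
                     "ID=e2;Parent=g3", sep = "\t"),
               paste("chrT", ".", "CDS", 151, 350, ".", "+", ".",
                     "Parent=g3", sep = "\t")), gff)
  expect_error(load_locus(fa, gff), "exactly one exon")

  # unknown strand rejected
  bed_u <- file.path(dir, "nostrand.bed")
  writeLines(paste("chrT", 100, 300, "g4", 0, ".", sep = "\t"), bed_u)
  expect_error(load_locus(fa, bed_u), "strand")
})

test_that("FASTA write/read round-trips a construct", {
  m <- dna_molecule("frag7", rand_dna(321, 9))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_construct(m, fa, "fasta")
  back <- read_fasta_molecule(fa)
  expect_equal(back$seq, m$seq)
  expect_equal(back$id, "frag7")
  expect_error(write_construct(m, "/nonexistent-dir/x.fa", "fasta"),
               "cannot write")
})
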