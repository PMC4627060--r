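# Architecture of the three synthesis components and the screening primers.

lx <- make_locus(fixture_spec(101, locus_len = 12000))
locus <- lx$molecule
gene <- lx$gene
crit <- exon_interval(gene, 3)
lox_pt <- crit$start - 250L
cas_pt <- crit$end + 250L

test_that("cassette insert follows the published segment architecture", {
  cas <- design_cassette_insert(locus, cas_pt)
  # 6 + 100 + 34 + 71 + 60 + 34 + 18 + 34 + 100 + 6
  expect_equal(mol_len(cas), 463L)
  expect_equal(nrow(features_of(cas, "FRT")), 2L)
  expect_equal(nrow(features_of(cas, "loxP")), 1L)
  arms <- features_of(cas, "homology_arm")
  expect_equal(arms$end - arms$start, c(100L, 100L))
  # 5' arm copied verbatim from immediately 5' of the insertion site
  arm5 <- substr(cas$seq, arms$start[1] + 1, arms$end[1])
  expect_equal(arm5, substr(locus$seq, cas_pt - 100 + 1, cas_pt))
  arm3 <- substr(cas$seq, arms$start[2] + 1, arms$end[2])
  expect_equal(arm3, substr(locus$seq, cas_pt + 1, cas_pt + 100))
  # segment order: site, arm, FRT, Pgk1, BGHpA, FRT, spacer, loxP, arm, site
  expect_equal(cas$features$label,
               c("BamHI", "mini_arm_5p", "FRT", "Pgk1_5p_homology",
                 "BGHpA_3p_homology", "FRT", "spacer", "loxP", "mini_arm_3p",
                 "BamHI"))
})

test_that("cassette design rejects arms off the locus and internal release sites", {
  expect_error(design_cassette_insert(locus, 50L), "off the locus")
  expect_error(design_cassette_insert(locus, mol_len(locus) - 10L),
               "off the locus")
  bad <- design_parameters(spacer_seq = "AAAGGATCCAAAGGATCC")
  expect_error(design_cassette_insert(locus, cas_pt, bad),
               "BamHI site inside")
  # N inside an arm
  nl <- locus
  substr(nl$seq, cas_pt - 20, cas_pt - 20) <- "N"
  expect_error(design_cassette_insert(nl, cas_pt), "N bases")
})

test_that("loxP oligo is 200 nt with the site between 83-nt flanks", {
  ol <- design_lox_oligo(locus, lox_pt)
  expect_equal(mol_len(ol), 200L)
  lox <- features_of(ol, "loxP")
  expect_equal(c(lox$start, lox$end), c(83L, 117L))
  expect_equal(attr(ol, "phosphorothioate_bonds"), c(1L, 2L, 198L, 199L))
  expect_equal(substr(ol$seq, 1, 83),
               substr(locus$seq, lox_pt - 83 + 1, lox_pt))
  expect_equal(substr(ol$seq, 118, 200),
               substr(locus$seq, lox_pt + 1, lox_pt + 83))
  # parameter arithmetic
  ol2 <- design_lox_oligo(locus, lox_pt,
                          design_parameters(oligo_flank_len = 50))
  expect_equal(mol_len(ol2), 134L)
  lox2 <- features_of(ol2, "loxP")
  expect_equal(c(lox2$start, lox2$end), c(50L, 84L))
  expect_error(design_lox_oligo(locus, 40L), "off the locus")
})

test_that("retrieval insert carries NotI + two 200-nt arms around XhoI", {
  iv <- c(lox_pt - 3000L, cas_pt + 3000L)
  ri <- design_retrieval_insert(locus, iv)
  expect_equal(mol_len(ri), 8L + 200L + 6L + 200L)
  arms <- features_of(ri, "homology_arm")
  expect_equal(arms$end - arms$start, c(200L, 200L))
  expect_equal(substr(ri$seq, 9, 208),
               substr(locus$seq, iv[1] + 1, iv[1] + 200))
  expect_equal(substr(ri$seq, 215, 414),
               substr(locus$seq, iv[2] - 200 + 1, iv[2]))
  expect_error(design_retrieval_insert(locus, c(100L, 450L)), "shorter")
})

test_that("screening primers sit outside the arms and shift by exactly 34", {
  pp <- design_screen_primers(locus, lox_pt)
  expect_equal(pp$targeted_amplicon, pp$wt_amplicon + 34L)
  expect_lte(pp$fwd_start + pp$primer_len, lox_pt - 83L)
  expect_gte(pp$rev_end - pp$primer_len, lox_pt + 83L)
  expect_equal(pp$wt_amplicon, pp$rev_end - pp$fwd_start)
  # predictions verified by simulated PCR before/after oligo insertion
  expect_equal(pcr(locus, pp$fwd, pp$rev), pp$wt_amplicon)
  targeted <- recombineer_ss(locus, design_lox_oligo(locus, lox_pt))
  expect_equal(pcr(targeted, pp$fwd, pp$rev), pp$targeted_amplicon)
  # a manual primer overlapping an arm is rejected (arm edge minus 1)
  expect_error(
    design_screen_primers(locus, lox_pt, fwd_start = lox_pt - 83L - 19L),
    "inside the oligo homology arms"
  )
  # a manual primer that is not unique in the locus is rejected
  dup <- locus
  dup$seq <- paste0(dup$seq, substr(dup$seq, 201, 420))
  expect_error(design_screen_primers(dup, lox_pt, fwd_start = 250L),
               "not unique")
})

test_that("every homology segment in a bundle is an exact locus substring", {
  for (seed in c(201, 202, 203)) {
    fx <- make_end_to_end_fixture(seed)
    lseq <- fx$locus$seq
    segs <- list()
    cas <- fx$bundle$cassette_insert
    for (i in which(cas$features$kind == "homology_arm")) {
      segs <- c(segs, substr(cas$seq, cas$features$start[i] + 1,
                             cas$features$end[i]))
    }
    ol <- fx$bundle$lox_oligo_designed
    segs <- c(segs, substr(ol$seq, 1, 83), substr(ol$seq, 118, 200))
    ri <- fx$bundle$retrieval_insert
    for (i in which(ri$features$kind == "homology_arm")) {
      segs <- c(segs, substr(ri$seq, ri$features$start[i] + 1,
                             ri$features$end[i]))
    }
    for (s in segs) expect_true(grepl(s, lseq, fixed = TRUE))
  }
})
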