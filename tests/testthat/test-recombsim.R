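# Simulated DNA transactions: recombineering, gap repair, Cre/Flp
# recombination, digestion, PCR and fingerprint comparison.

test_that("double-stranded recombineering replaces the spanned region", {
  # cassette insert on its carrier + the 1.9 kb fragment sharing the 71-
  # and 60-nt internal homologies: insert region 463 - 131 + 1900 = 2232
  fx <- make_end_to_end_fixture(301)
  prep <- recombineer_ds(fx$puc_carrier, fx$neo_fragment)
  expect_equal(mol_len(prep), mol_len(fx$puc_carrier) - 131L + 1900L)
  backbone_len <- mol_len(fx$puc_carrier) - 463L
  expect_equal(mol_len(prep) - backbone_len, 2232L)

  # no-op: a cassette identical to the spanned region leaves the target
  # unchanged
  locus <- fx$locus
  piece <- dna_molecule("piece", substr(locus$seq, 2001, 2400))
  expect_equal(recombineer_ds(locus, piece)$seq, locus$seq)

  # an arm present twice in the target is an ambiguity error
  dup <- dna_molecule("dup", paste0(locus$seq, substr(locus$seq, 2001, 2400)),
                      "linear")
  expect_error(recombineer_ds(dup, piece), "multiple positions")
  # absent arms are reported as not found
  alien <- dna_molecule("alien", rand_dna(400, 77))
  expect_error(recombineer_ds(locus, alien), "not found")
})

test_that("ssODN insertion adds exactly the payload, strand-symmetrically", {
  lx <- make_locus(fixture_spec(302, locus_len = 10000))
  locus <- lx$molecule
  pt <- exon_interval(lx$gene, 3)$start - 200L
  oligo <- design_lox_oligo(locus, pt)
  prod <- recombineer_ss(locus, oligo)
  expect_equal(mol_len(prod), 10034L)
  # prefix/suffix unchanged, loxP inserted at the intended point
  expect_equal(substr(prod$seq, 1, pt), substr(locus$seq, 1, pt))
  expect_equal(substr(prod$seq, pt + 1, pt + 34), LOXP_SEQ)
  expect_equal(substr(prod$seq, pt + 35, mol_len(prod)),
               substr(locus$seq, pt + 1, mol_len(locus)))
  expect_equal(recombineer_ss(locus, reverse_complement(oligo))$seq, prod$seq)

  # flanks matching 500 nt apart: the interval is replaced by the payload
  gap_oligo <- dna_molecule("gap", paste0(
    substr(locus$seq, pt - 83 + 1, pt), LOXP_SEQ,
    substr(locus$seq, pt + 501, pt + 583)
  ))
  repl <- recombineer_ss(locus, gap_oligo)
  expect_equal(mol_len(repl), mol_len(locus) - 500L + 34L)
})

test_that("recombineering products obey length conservation with features intact", {
  for (seed in c(311, 312)) {
    fx <- make_end_to_end_fixture(seed)
    bac <- fx$bac$molecule
    released <- release_cassette(recombineer_ds(fx$puc_carrier,
                                                fx$neo_fragment),
                                 "BamHI")
    tr <- attr(recombineer_ds(bac, released), "trace")
    prod <- recombineer_ds(bac, released)
    expect_equal(mol_len(prod),
                 mol_len(bac) - tr$replaced_span + tr$payload_len)
    # payload features arrived: 2 FRT + 1 loxP from the cassette
    expect_equal(nrow(features_of(prod, "FRT")), 2L)
    co <- recombineer_ss(prod, fx$bundle$lox_oligo)
    expect_equal(mol_len(co), mol_len(prod) + 34L)
    expect_equal(nrow(features_of(co, "loxP")), 2L)
  }
})

test_that("gap repair retrieves the interval with each arm counted once", {
  # 5,000-nt linearized vector with 200-nt terminal arms + 8,000-nt
  # interval whose ends are the arms: circular product of 12,600 nt
  set.seed(41)
  tgt_seq <- rand_dna(9000, 41)
  tgt <- dna_molecule("tgt", tgt_seq, "circular",
                      features = feature("marker", 4000, 4500, "+", "inside"))
  s <- 500L
  e <- 8500L
  arm5 <- substr(tgt_seq, s + 1, s + 200)
  arm3 <- substr(tgt_seq, e - 200 + 1, e)
  vec <- dna_molecule("vec", paste0(arm3, rand_dna(4600, 42), arm5))
  prod <- gap_repair(tgt, vec)
  expect_equal(mol_len(prod), 5000L + 8000L - 2L * 200L)
  expect_equal(prod$topology, "circular")
  # features inside the retrieved interval are carried over
  expect_equal(sum(prod$features$label == "inside"), 1L)
  # retrieved region starts at the origin: first 200 bases are the 5' arm
  expect_equal(substr(prod$seq, 1, 200), arm5)

  # both arms matching the same position: degenerate interval
  vec_bad <- dna_molecule("bad", paste0(arm5, rand_dna(4600, 43), arm5))
  expect_error(gap_repair(tgt, vec_bad), "degenerate")
  # outward-facing arms on a linear target
  lin <- dna_molecule("lin", tgt_seq, "linear")
  vec_out <- dna_molecule("out", paste0(arm5, rand_dna(4600, 44), arm3))
  expect_error(gap_repair(lin, vec_out), "outward")
})

test_that("direct-repeat recombination excises between site midpoints", {
  # 10,000-nt circle, two direct loxP around a 1,000-nt segment:
  # circles of 1,034 and 8,966 nt, one full site each
  set.seed(51)
  core <- rand_dna(1000, 51)
  rest <- rand_dna(10000 - 1000 - 68, 52)
  seqc <- paste0(LOXP_SEQ, core, LOXP_SEQ, rest)
  m <- dna_molecule("c", seqc, "circular", features = rbind(
    feature("loxP", 0, 34, "+", "lox1"),
    feature("loxP", 1034, 1068, "+", "lox2"),
    feature("marker", 200, 300, "+", "inner"),
    feature("marker", 2000, 2500, "+", "outer")
  ))
  out <- site_specific_recombine(m, "loxP")
  lens <- sort(unname(vapply(out, mol_len, integer(1))))
  expect_equal(lens, c(1034L, 8966L))
  expect_equal(sum(lens), mol_len(m))  # length conservation
  for (p in out) expect_equal(nrow(features_of(p, "loxP")), 1L)
  expect_equal(sum(out$excised$features$label == "inner"), 1L)
  expect_equal(sum(out$retained$features$label == "outer"), 1L)
  # the hybrid site is a full intact loxP
  sx <- features_of(out$excised, "loxP")
  expect_equal(substr(out$excised$seq, sx$start + 1, sx$end), LOXP_SEQ)

  # rotation invariance of the product set
  out_r <- site_specific_recombine(rotate_molecule(m, 4321L), "loxP")
  expect_equal(sort(unname(vapply(out_r, mol_len, integer(1)))), lens)
  expect_true(same_sequence(out_r$excised, out$excised))

  # linear input: shortened molecule + excised circle
  ml <- m
  ml$topology <- "linear"
  outl <- site_specific_recombine(ml, "loxP")
  expect_equal(outl$retained$topology, "linear")
  expect_equal(outl$excised$topology, "circular")
  expect_equal(mol_len(outl$retained) + mol_len(outl$excised), mol_len(ml))

  expect_error(site_specific_recombine(dna_molecule("x", seqc, "circular"),
                                       "loxP"), "at least two")
})

test_that("inverted sites invert the intervening segment and keep both sites", {
  set.seed(61)
  core <- rand_dna(500, 61)
  seqc <- paste0(rand_dna(300, 62), LOXP_SEQ, core, oracle_revcomp(LOXP_SEQ),
                 rand_dna(300, 63))
  m <- dna_molecule("inv", seqc, "linear", features = rbind(
    feature("loxP", 300, 334, "+", "lox1"),
    feature("loxP", 834, 868, "-", "lox2"),
    feature("marker", 400, 450, "+", "mid")
  ))
  out <- site_specific_recombine(m, "loxP")
  inv <- out$inverted
  expect_equal(mol_len(inv), mol_len(m))
  expect_equal(nrow(features_of(inv, "loxP")), 2L)
  # midpoint crossover: the segment between site midpoints is
  # reverse-complemented in place
  expect_equal(substr(inv$seq, 318, 851),
               oracle_revcomp(substr(m$seq, 318, 851)))
  md <- inv$features[inv$features$label == "mid", ]
  expect_equal(md$strand, "-")
  expect_equal(md$end - md$start, 50L)
  # involution: inverting again restores the original sequence
  back <- site_specific_recombine(inv, "loxP")$inverted
  expect_equal(back$seq, m$seq)
})

test_that("digest follows the topology fragment rules and band arithmetic", {
  fx <- make_end_to_end_fixture(303)
  prep <- recombineer_ds(fx$puc_carrier, fx$neo_fragment)
  # mixed prep (parent + recombined): three bands - backbone, synthesized
  # insert, size-shifted cassette
  bands <- sort(unique(c(digest(fx$puc_carrier, "BamHI")$lengths,
                         digest(prep, "BamHI")$lengths)))
  expect_length(bands, 3L)
  # cut at the site 5' end: each insert fragment carries one flanking site
  expect_equal(bands[1:2], c(463L - 6L, 2232L - 6L))

  # circular molecule with one site: a single full-length fragment
  circ1 <- dna_molecule("c1", paste0("GAATTC", strrep("ACGGTT", 499)),
                        "circular")
  d1 <- digest(circ1, "EcoRI")
  expect_equal(d1$lengths, 3000L)
  # linear molecule with zero sites: itself
  lin0 <- dna_molecule("l0", rand_dna(800, 72))
  expect_equal(digest(lin0, "NotI")$lengths, 800L)
  expect_identical(digest(lin0, "NotI")$fragments[[1]]$seq, lin0$seq)
  # linear with n cuts -> n+1 fragments; lengths sum to the molecule
  lin <- dna_molecule("l", paste0(rand_dna(500, 73), "ACTAGT",
                                  rand_dna(700, 74), "ACTAGT",
                                  rand_dna(300, 75)))
  d <- digest(lin, "SpeI")
  expect_length(d$lengths, 3L)
  expect_equal(sum(d$lengths), mol_len(lin))
  expect_error(digest(lin, "FakeIII"), "unknown")
})

test_that("PCR predicts the 34-base size shift and topology semantics", {
  fx <- make_end_to_end_fixture(304)
  pp <- fx$bundle$screen_primers
  before <- pcr(fx$locus, pp$fwd, pp$rev)
  after <- pcr(recombineer_ss(fx$locus, fx$bundle$lox_oligo_designed),
               pp$fwd, pp$rev)
  expect_equal(after - before, 34L)
  # polyclonal well: union of amplicons from a template mixture
  both <- pcr(list(fx$locus,
                   recombineer_ss(fx$locus, fx$bundle$lox_oligo_designed)),
              pp$fwd, pp$rev)
  expect_equal(both, c(before, after))
  # absent forward primer: no product
  expect_length(pcr(fx$locus, strrep("ACGT", 5), pp$rev), 0L)
  # divergent primers: nothing on a linear molecule, a wrap-around product
  # on the same molecule circularized (verified against direct arithmetic)
  s <- fx$locus$seq
  f2 <- substr(s, 3001, 3020)
  r2 <- oracle_revcomp(substr(s, 1001, 1020))
  lin <- dna_molecule("lin", s, "linear")
  circ <- dna_molecule("circ", s, "circular")
  expect_length(pcr(lin, f2, r2, max_amplicon = 30000L), 0L)
  expect_equal(pcr(circ, f2, r2, max_amplicon = 30000L),
               mol_len(circ) - 3000L + 1020L)
  expect_error(pcr(lin, "ACGTACGTACGT", r2), "at least 15")
})

test_that("fragment-set comparison flags rearranged clones", {
  expect_true(compare_fragment_sets(c(500, 1500, 3000),
                                    c(500, 1500, 3000))$identical_within_tolerance)
  m <- compare_fragment_sets(3000, 3100, tolerance = 0.05)
  expect_true(m$identical_within_tolerance)  # 100/3100 < 0.05
  expect_false(compare_fragment_sets(3000, 3200,
                                     tolerance = 0.05)$identical_within_tolerance)
  # simulated rearranged BAC: SpeI fingerprint differs from the intact clone
  lx <- make_locus(fixture_spec(305, locus_len = 15000))
  intact <- make_mock_bac(lx$molecule, "T7_to_Sp6", seed = 8)
  rearr <- make_mock_bac(lx$molecule, "T7_to_Sp6", seed = 8,
                         inject_rearrangement = TRUE)
  fp_ref <- digest(intact$molecule, "SpeI")$lengths
  fp_obs <- digest(rearr$molecule, "SpeI")$lengths
  cmp <- compare_fragment_sets(fp_obs, fp_ref, tolerance = 0.02)
  expect_false(cmp$identical_within_tolerance)
  expect_true(compare_fragment_sets(fp_ref, fp_ref,
                                    tolerance = 0.02)$identical_within_tolerance)
})
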