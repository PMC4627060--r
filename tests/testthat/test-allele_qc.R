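# Frameshift/premature-stop reasoning and structural checks of the
# simulated alleles.

test_that("mod-3 arithmetic drives the frameshift flag", {
  exons <- data.frame(start = c(0L, 500L, 1000L), end = c(200L, 621L, 1300L))
  cds <- data.frame(start = c(60L, 500L, 1000L), end = c(200L, 621L, 1160L))
  g121 <- gene_model("g", "+", exons, cds, 2L)
  rep <- check_conditional_null(g121, 2L)
  expect_equal(rep$removed_cds_len, 121L)
  expect_true(rep$frameshift)  # 121 mod 3 = 1

  exons$end[2] <- 620L
  cds$end[2] <- 620L
  g120 <- gene_model("g", "+", exons, cds, 2L)
  expect_warning(rep2 <- check_conditional_null(g120, 2L), "multiple of 3")
  expect_equal(rep2$removed_cds_len, 120L)
  expect_false(rep2$frameshift)
})

test_that("edge exons and non-coding exons are rejected", {
  exons <- data.frame(start = c(0L, 500L, 1000L, 1500L),
                      end = c(200L, 621L, 1300L, 1700L))
  cds <- data.frame(start = c(60L, 500L, 1000L), end = c(200L, 621L, 1160L))
  g <- gene_model("g", "+", exons, cds)
  expect_error(check_conditional_null(g, 1L), "first or last coding exon")
  expect_error(check_conditional_null(g, 3L), "first or last coding exon")
  expect_error(check_conditional_null(g, 4L), "no CDS")
  expect_error(check_conditional_null(g, integer()), "non-empty")
})

test_that("premature stop position matches a brute-force translation scan", {
  fx <- make_end_to_end_fixture(401)
  rep <- check_conditional_null(fx$gene, fx$spec$critical_exon, fx$locus)
  expect_true(rep$frameshift)
  # independent oracle: splice, translate with a hand-rolled codon table,
  # scan for the first stop
  post <- oracle_spliced_cds(fx$gene, fx$locus$seq, fx$spec$critical_exon)
  aa <- oracle_translate(post)
  expect_equal(rep$first_premature_stop,
               as.integer(regexpr("*", aa, fixed = TRUE)))
})

test_that("frameshift flag equals the splice-and-translate oracle on many genes", {
  set.seed(99)
  n_checked <- 0L
  for (seed in 1:70) {
    n_ex <- sample(4:6, 1)
    lx <- make_locus(fixture_spec(seed + 5000, locus_len = 8000,
                                  n_exons = n_ex,
                                  critical_exon = sample(2:(n_ex - 1), 1),
                                  gene_strand = sample(c("+", "-"), 1)))
    for (removed in 2:(n_ex - 1)) {
      got <- suppressWarnings(check_conditional_null(lx$gene, removed))
      want <- oracle_frameshift_check(lx$gene, lx$molecule$seq, removed)
      expect_equal(got$frameshift, want)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("allele structure reflects each stage of the workflow", {
  fx <- make_end_to_end_fixture(402)
  res <- run_cko_pipeline(fx)
  v <- verify_allele_structure(res$cko_vector, fx$gene, fx$params)
  expect_equal(c(v$lox_count, v$frt_count), c(2L, 2L))
  # arms are the designed 3000 bases, plus at most a few bases of chance
  # homology extension at the retrieval junctions
  expect_gte(v$arm5_len, 3000L)
  expect_lte(v$arm5_len, 3030L)
  expect_gte(v$arm3_len, 3000L)
  expect_lte(v$arm3_len, 3030L)
  expect_true(v$es_arm_in_range)
  expect_true(v$critical_exon_floxed)

  vf <- verify_allele_structure(res$post_flp, fx$gene, fx$params)
  expect_equal(c(vf$lox_count, vf$frt_count), c(2L, 1L))

  vc <- verify_allele_structure(res$post_cre, fx$gene, fx$params)
  expect_equal(c(vc$lox_count, vc$frt_count), c(1L, 0L))
  # the critical exon left with the excised circle
  crit_lab <- paste0(fx$gene$gene_id, ":exon", fx$spec$critical_exon)
  expect_false(any(res$post_cre$features$label == crit_lab))
  expect_true(any(res$post_cre_excised$features$label == crit_lab))

  expect_error(verify_allele_structure(fx$locus), "no loxP")
})

test_that("short ES arms raise a range warning", {
  fx <- make_end_to_end_fixture(403, arm_target = 2000L)
  res <- run_cko_pipeline(fx)
  expect_warning(v <- verify_allele_structure(res$cko_vector, fx$gene,
                                              fx$params),
                 "outside the recommended range")
  expect_false(v$es_arm_in_range)
  expect_gte(v$arm5_len, 2000L)
  expect_lte(v$arm5_len, 2030L)
})

test_that("pipeline excision matches the gene-model arithmetic", {
  # Cre removes the floxed segment (genomic interval between the two
  # insertion points, the residual FRT + spacer, and one loxP copy),
  # carrying the critical exon with it, on either gene strand
  for (gs in c("+", "-")) {
    fx <- make_end_to_end_fixture(404, gene_strand = gs)
    res <- run_cko_pipeline(fx)
    removed_len <- cds_len_in_exons(fx$gene, fx$spec$critical_exon)
    between <- abs(fx$cassette_point - fx$lox_point)
    expect_equal(mol_len(res$post_flp) - mol_len(res$post_cre),
                 between + 34L + 18L + 34L)
    expect_true(removed_len %% 3L != 0L)
    # the residual FRT sits inside the floxed segment, so the KO allele
    # analog carries no FRT and one loxP
    expect_equal(nrow(features_of(res$post_cre, "FRT")), 0L)
    expect_equal(nrow(features_of(res$post_cre, "loxP")), 1L)
  }
})
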