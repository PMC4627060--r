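# cosbr

Design and in-silico verification of conditional knockout (CKO) gene
targeting vectors built by **co-selection BAC recombineering (CoSBR)**,
plus the screening statistics of the polyclonal 96-well protocol.

## The problem

A conditional knockout allele flanks ("floxes") a critical exon with two
loxP sites so Cre can excise it later; the exon is chosen so that splicing
of the remaining exons frameshifts into a premature stop. Building the
targeting vector by classical recombineering takes four engineering steps
with extra plasmid-separation work after each one. CoSBR collapses this to
two steps performed directly in the BAC:

1. **Co-targeting** — electroporate the BAC-carrying cells simultaneously
   with (a) a double-stranded, kanamycin-selectable
   `FRT–Pgk1-em7-neo–FRT–spacer–loxP` cassette flanked by 100-bp mini
   homology arms, and (b) a non-selected 200-nt single-stranded oligo that
   carries the second loxP between two 83-nt homologies. Selecting for the
   cassette enriches for clones that also picked up the oligo.
2. **Retrieval (gap repair)** — capture the modified genomic interval into
   an XhoI-linearized retrieval vector through two 200-bp terminal arms,
   yielding the final CKO vector whose ES-cell homology arms (generally
   2.5–3.5 kb) are the genomic sequence outside the two loxP sites.

Because only ~0.2–6 % of kanamycin-resistant colonies carry the oligo,
colonies are screened in bulk: the culture is distributed into a 96-well
plate (~1–4 founders per well, wells are polyclonal) and scored by a PCR
amplicon that grows by exactly 34 bp when the loxP is present.

This package does everything about that workflow which is computable at a
desk:

* **designer** — emits the three synthesis components (cassette insert,
  loxP oligo with phosphorothioate annotations, retrieval insert) and the
  screening primer pair, with the exact published architecture.
* **strandlogic** — picks the lagging-strand version of the oligo from the
  BAC insert orientation (pBACe3.6 replicates unidirectionally from OriS;
  a gene transcribed with the T7→Sp6 arrow has its coding strand as the
  lagging strand).
* **recombsim** — simulates every DNA transaction exactly: ds/ss
  recombineering (exact, unique homology matching), gap repair, Cre/Flp
  recombination (midpoint crossover), restriction digestion, PCR, and
  restriction-fingerprint comparison.
* **allele_qc** — verifies vector structure (site counts, ES arm lengths,
  exon floxed) and that excising the critical exon frameshifts
  (`removed CDS length mod 3 ≠ 0`), with a translate-and-scan for the
  first premature stop.
* **platestats** — screening arithmetic and the Poisson founder model:
  wells score positive with probability `1 − exp(−λ·f)` where
  `λ = colonies/wells` and `f` is the per-colony co-targeting frequency;
  the inverse `f̂ = −ln(1 − positives/wells)/λ` converts well counts back
  to per-colony frequencies. Pooling two independent BAC clones reduces
  the risk of an all-bad project from ~10 % to ~1 % (`0.1² = 0.01`).
* **fixtures** — deterministic generators for synthetic loci, gene models
  and mock BAC/carrier plasmids, including an independently
  string-assembled expected final vector used as a brute-force oracle.

## Worked example

```r
library(cosbr)

fx  <- make_end_to_end_fixture(17)   # synthetic locus + gene + mock BAC
fx$bundle$strand_call
#> <strand_call> lagging strand = coding_strand
#>   gene synthgene17 transcribed on '+' ... insert orientation T7_to_Sp6 ...

fx$bundle$screen_primers
#> <primer_pair> fwd ACGTCCGTTTAGGCGTCTGA / rev GTTGTTAGGAGTGCCTCTAC; wt 206 bp, targeted 240 bp

res <- run_cko_pipeline(fx)          # prep -> co-target -> gap repair -> Flp -> Cre
res$mixed_prep_bands                 # BamHI digest of the mixed miniprep
#> [1]  457 2226 2692                 # ~0.5 kb insert, ~2.2 kb shifted cassette, backbone

verify_allele_structure(res$cko_vector, fx$gene, fx$params)
#> <allele_report>
#>   lox_count: 2
#>   frt_count: 2
#>   arm5_len: 3000
#>   arm3_len: 3000
#>   es_arm_in_range: TRUE
#>   critical_exon_floxed: TRUE

same_sequence(res$cko_vector, fx$expected_cko)   # vs string-assembled oracle
#> [1] TRUE

frequency_summary(23, 369)           # colony screen: 23 loxP+ of 369 kan-R
#> <freq_summary> 23/369 = 6.2% (6%)

estimate_cotargeting_freq(plate_screen(369, 96, 23))  # 96-well screen
#> <freq_estimate> f = 0.0713 (CI 0.0448-0.1071), lambda = 3.84

pooled_bac_failure_risk(0.10, 2)
#> [1] 0.01
```

The wild-type amplicon (206 bp) and the targeted amplicon (240 bp) differ
by exactly the 34-bp loxP insertion; `pcr()` on the simulated co-targeted
BAC reproduces both numbers. The allele report confirms the final vector
carries 2 loxP + 2 FRT sites with 3.0-kb ES homology arms and the critical
exon between the loxP sites; after simulated Flp the neo marker is gone
(1 FRT left) and after Cre the exon and residual FRT are excised with a
single loxP remaining.

A thin CLI wraps the same functions:

```sh
cosbr make-fixture --seed 17 --out-dir fx/
cosbr design   --config fx/config.yaml --out-dir out/
cosbr simulate --config fx/config.yaml --out-dir out/
cosbr qc       --vector out/cko_vector.gb --config fx/config.yaml --out-dir out/
cosbr stats    --colonies 369 --wells 96 --positives 23
```

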