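---
title: "Models and methods behind the cosbr toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cosbr toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosbr)
```

# What is being modeled

Co-selection BAC recombineering builds a conditional-knockout targeting
vector in two wet-lab steps: simultaneous introduction of a selectable
`FRT–neo–FRT–spacer–loxP` cassette and a non-selected single-stranded
loxP oligo into a BAC, then gap-repair retrieval of the modified interval
into a linearized vector. Everything about that workflow that is a
deterministic function of sequence — the architecture of the synthesis
components, the sequence of every intermediate, the gel band sizes, the
PCR size shift used for screening — is simulated here exactly, at
single-base resolution. The only stochastic element of the protocol, the
distribution of founder colonies across a 96-well plate, is modeled
probabilistically.

# Design components and their parameters

`design_parameters()` collects the tunable lengths (all in bases) with
the architecture defaults:

| parameter | default | role |
|---|---|---|
| `mini_arm_len` | 100 | cassette mini homology arms |
| `oligo_flank_len` | 83 | oligo flank homologies (200-nt oligo total) |
| `site_len` | 34 (fixed) | loxP and FRT recognition sites |
| `pgk1_homology_len` / `bghpa_homology_len` | 71 / 60 | homologies through which the neo fragment enters the synthesized insert |
| `spacer_len` | 18 | spacer between 3′ FRT and cassette loxP |
| `retrieval_arm_len` | 200 | gap-repair arms |
| `phosphorothioate_per_end` | 2 | protected terminal bonds per oligo end (annotation only) |
| `es_arm_range` | 2500–3500 | acceptable ES-cell homology arm lengths |
| `min_arm` | 50 | seed length for simulated homology matching |

With 6-bp release sites the cassette insert is
`6 + 100 + 34 + 71 + 60 + 34 + 18 + 34 + 100 + 6 = 463` nt, and after the
1.9-kb neo fragment recombines through the 71/60-nt homologies the insert
region becomes `463 − 131 + 1900 = 2232` nt.

The loxP and FRT constants are the canonical 34-bp literature sequences;
the Pgk1-5′ and BGHpA-3′ homology segments are fixed *synthetic* stand-in
sequences (only their exact sharing between the cassette insert and the
neo fragment matters to the simulation). All are overridable through
`design_parameters()`.

**Orientation.** All components are designed in *gene* orientation: for a
minus-strand gene the emitted cassette reads 5′→3′ on the genomic minus
strand. This keeps the `FRT–neo–FRT–spacer–loxP` order correct relative
to the gene, so the residual post-Flp FRT lies inside the floxed segment
and is removed together with the critical exon by Cre — the published
allele architecture. Both loxP sites are always direct repeats, as Cre
excision requires. The lagging/leading choice (`orient_oligo()`) is then a
pure reverse-complement of the designed sequence and never changes the
simulated product, which is exactly the in-vivo situation: strand choice
affects efficiency, not the recombinant.

**Screening primers.** The protocol constrains primers only to bind
outside the oligo homology arms and to give a small amplicon whose size
shifts by 34 bp. The picker scans outward from the arm edges for the
nearest 20-mer with 40–60 % GC that is unique in the locus (both
strands). No thermodynamic model is used — melting behavior adds nothing
to a size-shift readout and would make designs non-deterministic.

# The recombineering model

Homology matching is **exact-substring and unique**:

* each terminal arm of a donor is seeded by its first/last `min_arm`
  (default 50) bases, located in the target, and extended maximally while
  donor and target agree;
* a seed matching more than one position is an error (ambiguity is never
  resolved by choice);
* both arms must be found on the same strand of the target, in consistent
  order; the donor is reverse-complemented automatically when its arms
  match the minus strand.

Released fragments carry non-homologous terminal remnants (a BamHI site
on the released cassette, the XhoI half-sites on the linearized retrieval
vector). The engine tolerates up to `end_slack` (20) unmatched terminal
bases when seeding and **drops everything outside the arm matches** from
the product, recording the dropped bases in the junction trace. This is
the simulator's answer to the question of whether those bases persist:
recombination proceeds through the homology, so they cannot.

Because extension runs as far as identity runs, an arm can extend a few
bases beyond its designed length when the adjacent vector base happens to
equal the adjacent genomic base (probability ¼ per base). The product
sequence is unaffected — the extra bases are identical on both sides —
but reported junction coordinates and ES-arm measurements can exceed the
nominal design by these few bases; tests bound rather than pin them.

Circular targets are handled by rotating the stored origin to the 5′ arm
match before linear surgery; every interval operation is
rotation-invariant, which the test suite asserts by re-running operations
on rotated molecules.

**Site-specific recombination** (Cre/loxP, Flp/FRT) crosses over at the
site midpoints, so each product carries one full, intact 34-bp hybrid
site: direct repeats excise (circular input → two circles, one site each;
linear input → shortened molecule + excised circle), inverted repeats
invert the intervening segment. Total length and site count are
conserved. On a circle the retained/excised labels follow the stored
representation (the arc between the first and second site is "excised");
the pipeline identifies the biologically relevant product by its marker
features, never by arc labels.

**Digestion** cuts at the 5′ end of the recognition site (all six built-in
enzymes are palindromic, so a single-strand scan is complete). Under this
convention the mixed miniprep digest shows the backbone plus a 457-nt and
a 2226-nt insert band — each fragment carries one of the two flanking
sites — i.e. the ~0.5-kb and ~2.2-kb bands of the release gel. Fragment
lengths always sum to the molecule length (n cuts → n+1 fragments linear,
n fragments circular).

**PCR** is exact-match primer binding with no mismatch or thermodynamic
model; one amplicon per convergent pair within `max_amplicon` (default
5000), wrap-around amplicons allowed on circles. A polyclonal well is a
*set* of template molecules; `pcr()` on a list returns the union of
amplicon lengths, reproducing the two-band pattern of mixed wells. The
within-well competition caveat of the protocol (kan-resistant bacteria
must dominate before screening) is a culturing instruction, not sequence
arithmetic, and is deliberately not modeled.

# The 96-well founder model

Distributing a transformation of `C` colonies into `W` wells seeds each
well with a Poisson number of founders, `λ = C/W` (the observed regime is
131–463 colonies per plate, λ ≈ 1.4–4.8). If each founder independently
carries the co-targeted loxP with probability `f`, a well is
PCR-positive when it received at least one such founder:

$$P(\text{positive}) = 1 - e^{-\lambda f}.$$

The inverse converts a well count into a per-colony frequency:

$$\hat f = -\ln(1 - k/W)\,/\,\lambda,$$

clamped to [0, 1], with a confidence interval obtained by transforming an
exact Clopper–Pearson interval on `k/W`. A saturated plate (`k = W`)
leaves `f` unidentifiable and is an error. The plug-in estimator carries
a second-order (delta-method) bias
$\operatorname{Var}(\hat p) / (2(1-\hat p)^2 \lambda)$ from the convexity
of $-\ln(1-p)$; it is negligible at low positivity and a percent-scale
effect near saturation. The parameter-recovery tests therefore compare
the mean estimate against the truth within three Monte-Carlo standard
errors *plus* this analytic bias term, which is the correct error budget
for this estimator rather than a loosened tolerance.

Frequencies are reported in both printed conventions: two significant
figures for per-colony tables (6.2, 0.65, 0.24) and whole percents for
well tables (36, 63), with the exact fraction always retained. Pooling
`n` independent BAC clones per project fails only when all are bad:
`risk = per_clone_bad^n`, e.g. `0.1² = 0.01`.

# What the synthetic fixtures emulate — and what they do not

`make_locus()` embeds a multi-exon gene (valid start/stop, no internal
in-frame stops, internal exons fully coding, critical exon forced off a
multiple of 3) in random sequence at a target GC; `make_mock_bac()`
assembles it with a ~3-kb backbone stub carrying Sp6/T7 ends and the
OriS origin with its replication-direction annotation. Design choices:

* **20-kb loci, not 100–200-kb BACs.** Nothing in the algorithms is
  length-sensitive; a `locus_len` override generates BAC-scale fixtures
  and one test runs the unchanged workflow at 120 kb.
* **BamHI/NotI/XhoI are scrubbed** from generated sequence (the release
  and linearization steps need them absent or unique), while
  SpeI/EcoRI/BglII occurrences stay natural so restriction fingerprints
  have realistic band counts.
* The backbone stub is random sequence with marker features, not a real
  vector sequence; only the orientation metadata is consumed by the
  strand logic.
* Every generator is a pure function of its seed.

Fixtures do **not** emulate repeats, segmental duplications, N-runs, GC
extremes, or oligo synthesis errors. Passing tests therefore demonstrate
the correctness of the sequence arithmetic and the statistics, not
robustness to repetitive genomic context — on real loci, the uniqueness
requirement will (correctly) reject arm placements inside repeats, and
arm positioning against conservation tracks remains the designer's manual
job, supplied as coordinates.

The end-to-end oracle is an *independent* construction: the expected
final vector is assembled by direct string concatenation of locus
substrings and constants, never by the simulator, and the pipeline
product must match it base-for-base. Circular products are compared up to
rotation and strand, since a circular duplex has neither a fixed origin
nor a canonical stored strand.

# Numerical conventions and degenerate inputs

* Internal coordinates are 0-based half-open; all user-facing reports are
  1-based inclusive (GenBank convention).
* Wrap-around features on circles are stored as `start > end` and
  normalized by rotation before arithmetic.
* loxP/FRT features are validated to be exactly 34 bp; N bases are
  accepted in loci but rejected inside any designed homology segment.
* Degenerate cases error rather than guess: ambiguous arms, outward or
  coincident retrieval arms, saturated plates, removal of first/last
  coding exons (the splice model needs flanking coding exons), excision
  of an exon with no CDS.
* An in-frame (mod-3) critical exon is a *warning*, not an error — the
  tool reports, the designer decides.

# Problem sizes used by the test suite

Chosen as the package's own test design: oracle equivalence over 100
seeded end-to-end fixtures at 20-kb scale (plus one 120-kb run);
frameshift flag versus an independently coded splice-and-translate oracle
on 200 generated genes on both strands; frequency recovery on 1000
simulated plates per condition over λ ∈ {1.4, 3.8, 4.8} × f ∈ {0.01,
0.06, 0.36}; Monte-Carlo validation of the positivity formula at 10^5
replicates. The whole suite runs in well under a minute per property
group on a single CPU.

# Known limitations

* No recombineering *efficiency* model: lagging-over-leading preference
  is reported qualitatively (the screening data contain a documented
  counter-example, so fitting a numeric model would overclaim), and
  multimer formation or mixed-clone segregation — the phenomena that
  motivate doing the work in the BAC — are not computable deliverables.
* No conservation- or repeat-aware placement of arms and loxP sites;
  coordinates are user input.
* No NMD prediction or protein-domain annotation of the truncated
  product; the null check is frame arithmetic plus premature-stop
  translation under simple exon concatenation.
* PCR screening ignores within-well template competition and polymerase
  limits; positivity is a sequence property of the template set.
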