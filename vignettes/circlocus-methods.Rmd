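---
title: "Characterizing a circRNA locus with circlocus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a circRNA locus with circlocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlocus)
```

# The problem

A circular RNA (circRNA) arises by backsplicing: a downstream splice
donor (SD) joins an upstream splice acceptor (SA), producing a covalently
closed circle whose only circle-specific sequence is the backsplice
junction. Characterizing such a locus computationally involves a series
of linked questions:

* Which reverse complementary matches (RCMs) between the two flanking
  introns could base-pair and promote circularization?
* Can the backsplice acceptor be mutated without touching any linear
  transcript — i.e. is a circRNA-specific knockout feasible?
* If the canonical acceptor is destroyed, which downstream cryptic AG
  could take over, and what does the shifted circle look like?
* Which junction-spanning oligos (shRNAs, probes, divergent primers)
  detect or deplete the circle without touching the linear isoforms?
* Does the circle encode a junction-spanning ORF, and which tryptic
  peptides would discriminate its product from the linear protein in a
  targeted (PRM) mass-spectrometry assay?

`circlocus` implements each of these steps behind one consistent data
model and ties them together in `runPipeline()`. A deterministic
synthetic-locus generator provides ground-truthed fixtures so the whole
chain is testable without any external annotation or sequence download.

# Coordinate frame

All internal coordinates are 1-based inclusive on the plus strand of the
reference, the native `IRanges` frame shared by every Bioconductor verb
the package imports. GFF3 uses this frame natively; BED (0-based
half-open) is converted in `writeBed6()`/`readBed6()` and nowhere else.
Using the ecosystem's own frame, with conversion confined to the BED
boundary, is the standard Bioconductor defence against off-by-one drift.

The *acceptor position* of an exon is its first transcribed base
(strand-aware); the intronic AG occupies the two bases immediately 5' of
it. First exons are transcription starts and have no acceptor, so
splice-acceptor usage is assessed over internal exons only. The same
convention anchors the cryptic-acceptor scan.

# Splice-site usage and knockout feasibility

`spliceSiteUsage()` asks, for every transcript, whether the backsplice
acceptor or donor coincides with one of the transcript's own internal
splice boundaries, and classifies sequence sharing (`exonic` when a
circularized exon intersects a transcript exon, `intronic` when the
circle lies inside the transcript span without exon overlap, `none`
otherwise). The verdict is computed against a *protected* transcript set
defaulting to all coding transcripts:

* `SA_MUTABLE` — no protected transcript uses the SA; an AG-to-TC edit
  of the acceptor depletes the circle specifically. This is the verdict
  the whole knockout strategy hinges on.
* `SD_MUTABLE` — the SA is shared but the SD is free.
* `SA_SHARED` — both sites are shared; site mutagenesis cannot be
  circle-specific.
* `NEITHER` — degenerate (no protected transcripts at all).

The orientation of these levels was a genuinely open choice; we resolved
it so that the verdict names the *editable* site when one exists and
otherwise names the blocking condition.

`crypticAcceptorScan()` models the observed fallback after acceptor
mutagenesis: the first 5'-AG-3' strictly downstream of the destroyed
site, within a configurable window (default 100 nt; biology gives no
hard bound, but reported cryptic acceptors are immediately juxtaposed,
and the window is exposed as a parameter). Usage *efficiency* of a
cryptic site is empirical and deliberately not predicted. The scan
returns `NO_CRYPTIC` (`found = FALSE`) rather than an error when no AG
exists in the window.

`rflpDigest()` predicts genotyping fragments: cut at every IUPAC motif
occurrence on the forward strand (Dde I: `CTNAG`, cut `C^TNAG`).
Heterozygotes are reported as the multiset union of the two alleles'
fragments with no intensity modelling; `discriminates` is simply whether
the allele multisets differ.

# RCM detection

`findRCM()` is a from-scratch seed-and-extend local aligner between the
upstream intron and the reverse complement of the downstream intron:

1. exact `word_size` seeds (words containing N never seed; N scores as a
   mismatch during extension);
2. per-diagonal ungapped extension of every seed under an X-drop rule
   (extension stops when the running score falls `xdrop` below its
   maximum, and ends at the maximal-score point);
3. chaining of nearby segments that advance in both coordinates (gap up
   to 25 nt), accepted only when an affine-gap global re-alignment of
   the joined region outscores both parts — this is where `gap_open`
   and `gap_extend` act (a gap of length g scores
   `gap_open + g * gap_extend`);
4. redundancy resolution (two hits conflict when they share more than
   half of either interval; the higher-scoring one wins) and filtering
   by `min_score` and `min_length`.

Default scoring mimics `blastn`: word 11, +2/−3, gaps −5/−2, X-drop 20,
minimum length 20, minimum score 30. There are no E-values; candidates
are ranked, as in practice, on length and percentage of
complementarity (`rankCandidates()`: length desc, identity desc, score
desc, position asc).

The `sensitive = TRUE` preset (word 5, +1/−3, minimum score 15, X-drop
10) mirrors the `blastn-short` style of task selection and exists for a
structural reason: a repeat of identity *q* with regularly spaced
substitutions has clean match runs of only about 1/(1−q) − 1 nt, so at
q = 0.85 no 11-mer word can seed. The +1/−3 scoring also sets the
extension break-even identity at 0.75, which keeps hit boundaries from
drifting into flanking random sequence and keeps reported identities
close to the repeat's true identity. Cross-intron mode is the default
(an RCM is by definition one segment per flanking intron); a same-intron
scan is just `findRCM(x, x)` and is left to the caller.

Downstream-intron coordinates are reported in the original (unreversed)
frame, and `rcmHitScore()` re-derives any hit's score from the reported
intervals alone, which the test suite uses as a consistency invariant.
`annotateRepeats()` attaches repeat names (e.g. SINE intervals) to hits
by closed-interval overlap of at least 1 nt.

# Circle-topology analyses

`buildCircle()` concatenates the chain exons 5'→3' (reverse complement
for minus-strand genes) and fixes the linearization origin at the
acceptor-side first base, so the junction is the boundary between the
last and first base. Every downstream result is rotation-invariant up to
a coordinate shift (`rotateCircle()` exists mainly for the tests that
verify this).

* `designJunctionShrna()` enumerates all `length`-nt windows spanning
  the junction with both arms ≥ `min_arm`, discards any window occurring
  verbatim in a provided linear mRNA (the selectivity guarantee is a
  hard substring check, not a heuristic), filters by GC, and ranks by GC
  closest to 0.45, arm symmetry, then an A/T at the guide 5' end. The
  ranking rules are explicit configuration: no thermodynamic scoring is
  attempted.
* `checkDivergentPrimers()` uses exact-match binding only (mismatch
  tolerance and melting temperature are out of scope) and computes the
  product on circular topology; a primer pair is circle-specific when no
  linear template supports a conventional forward-then-reverse product.
* `findCircularOrfs()` starts one ORF per ATG in any of the three
  circular frames and translates across the junction until a stop codon.
  Frames with no stop re-enter themselves; such *rolling* ORFs are
  reported (never silently dropped) with `laps = max_laps` (default 3,
  a runtime cap that matters only for pathological circles). Note that
  when the circle length is not a multiple of 3 the reading frame
  shifts at each lap, which is why ORF discovery is per-ATG rather than
  per-frame.
* `scanSeedSites()` implements the four canonical miRNA seed classes
  (8mer > 7mer-m8 > 7mer-A1 > 6mer, highest class per position,
  default floor 7mer-A1) on the circle extended by 7 wrap-around bases,
  so junction-spanning sites are found exactly once. No context score,
  conservation or free-energy term is computed.

# Peptides and PRM inclusion masses

`trypsinDigest()` cleaves C-terminal to K/R, suppressed before proline
by default, enumerating peptides with up to `max_missed_cleavages`
retained sites; protein C-termini are valid peptide C-termini regardless
of residue (a C-terminal peptide need not end in K/R).
`discriminativePeptides()` keeps the tryptic peptides of the
circle-specific ORF product that occur in no linear protein's digest
under the same parameters — these are the candidates a targeted PRM
assay would monitor.

Masses are exact monoisotopic sums: residue masses plus one water
(18.010565 Da), proton 1.007276 Da, `m/z = (M + z·1.007276)/z` reported
to five decimals. I and L are distinct residues of equal mass.
Carbamidomethyl (+57.021464) and oxidation (+15.994915) are available as
named modifications, but none is applied implicitly: PRM inclusion lists
target synthetic peptide standards, which carry unmodified cysteine even
when a companion database search uses fixed carbamidomethylation.
`feasibleCharges()` returns the charge states whose precursor m/z falls
inside the full-scan window (default 350–1500 m/z); on the bundled
fixture the highest feasible charge per peptide reproduces the
conventional charge assignment (3+ for the 11-mer, 2+ for the shorter
two).

# qPCR quantification

`relativeExpression()` averages technical replicates on the Ct scale,
forms ΔCt against the arithmetic mean of two housekeeper Cts (the
geometric mean of their linear abundances — the usual reading of
"average of two housekeepers"; the choice is recorded here and in the
output headers), converts with 2^(−ΔCt) at a fixed amplification
efficiency of 2, and rescales so the reference-condition mean is exactly
1. `circLinearRatio()` adds per-sample circular-to-linear ratios and a
per-condition predominance flag (mean ratio > 1). Inferential statistics
are intentionally out of scope.

# The synthetic-locus generator

`makeLocus()` draws a single deterministic stream from `spec@seed`
(saving and restoring the caller's RNG state) and assembles
flank–exon–intron segments with:

* canonical `GT..AG` intron boundaries — non-canonical splice sites are
  not generated;
* planted RCMs: the upstream segment is copied in reverse complement
  into the downstream intron with exactly
  `round((1 − identity) · length)` substitutions at evenly spaced
  positions, so the planted identity is exact and reproducible rather
  than a noisy target;
* a planted cryptic AG ending `cryptic_ag_offset` nt (default 4) into
  the first circularized exon, with any earlier exonic AG scrubbed so
  the planted one is the first downstream candidate;
* transcripts from explicit recipes (exon subsets, with consecutive
  indices fusable into one exon), exactly one canonical.

`makeMimicLocus()` is the bundled showcase fixture: eight exons, a
two-exon circularized block (520 nt), six transcripts with overlap
classes exonic×4 / intronic×2 in which only two non-protected minor
transcripts use the circ acceptor (so the knockout verdict is
`SA_MUTABLE`), seven planted RCMs of graded length (220→60 nt) in the
2-kb flanking introns, and a planted junction-spanning 95-aa ORF whose
first 84 residues match the linear protein's N terminus and whose
discriminative tryptic peptides include NLRGHNSESCK, GHNSESCK and
SPSRTFQS. Stop codons are planted in all three frames immediately 5' of
the ORF start, and the first codons after the junction are chosen so the
two off-frames terminate within a dozen nt — this makes the planted ORF
the unique long junction-spanning ORF, which is what the locus is
mimicking. `mirrorBundle()` produces the reverse-complemented
minus-strand image used by strand-handling tests.

`makeCtTable()` emulates qPCR readout as
`Ct = baseline − log2(expression) + N(0, noise_sd)` with baseline 30.

What the generator does *not* emulate: read data, expression counts,
spectra, repeat-family consensus sequences (SINE intervals are labels
over the planted RCMs, not Alu/B1-like sequence), branch points,
polypyrimidine tracts, or splice-site strength. Tests passing on these
fixtures therefore demonstrate algorithmic correctness on structurally
faithful loci, not performance on genomic sequence composition.

# Numerical choices and problem sizes

* The RCM oracle cross-checks run on ≤ 200-nt sequences where an
  exhaustive per-diagonal optimum is computable; recovery checks use 20
  bundles with 2-kb introns and one plant each (length 50–200 nt,
  identity 0.85–1.0), plus the 7-plant mimic locus for ranking. These
  sizes keep the full verification suite around a minute while covering
  the hardest seeding regime (identity 0.85).
* ORF-oracle and seed-oracle equivalence use 200 and 30–40 random
  circles respectively; shRNA selectivity is fuzzed over 100 random
  loci.
* Fold-change recovery is asserted as a mean absolute error bound of
  3·noise_sd/√n over 50 simulated tables (with most tables also
  individually inside the bound). The per-table estimator's standard
  deviation is √3·noise_sd/√n — noise enters through the target *and*
  both housekeepers — so demanding that every table meet a 3σ/√n bound
  would fail by chance alone in a long enough run; the aggregate form
  states the same recovery property stably.
* Ties in ranking and redundancy resolution are broken by genomic
  position so all outputs are deterministic; two runs with the same
  config and seed produce byte-identical TSVs.

# Limitations

* RCM detection is alignment-based only; no RNA–RNA duplex free energy,
  no repeat-family orientation logic, and no E-value statistics.
* Cryptic-acceptor prediction returns the first downstream AG; real
  acceptor choice integrates branch point and pyrimidine-tract context
  that is not modelled, and usage efficiency is not predicted.
* Primer checks are exact-match; a primer with a single mismatch is
  reported `NOT_FOUND` by design.
* The miRNA scan stops at canonical seed classes; no target-prediction
  score is replicated.
* The qPCR model fixes amplification efficiency at 2.0 per cycle with
  no standard-curve correction.
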