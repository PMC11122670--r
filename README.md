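# circlocus

Computational characterization of a circRNA-producing gene locus, for
molecular biologists designing circRNA-specific perturbations and the
assays to validate them.

A circular RNA (circRNA) arises by backsplicing: a downstream splice
donor (SD) joins an upstream splice acceptor (SA), and the resulting
covalently closed circle differs from every linear isoform of the locus
in exactly one place — the backsplice junction. `circlocus` answers the
questions that arise when a single circRNA is taken from annotation to
an in vivo loss-of-function model:

* **RCM mapping** — a from-scratch seed-and-extend local aligner
  (`findRCM`) detects reverse complementary matches between the two
  introns flanking the circularized exon block (exact word seeds,
  per-diagonal X-drop extension, affine-gap chaining, redundancy
  resolution) and ranks candidates on length and percentage of
  complementarity; repeat intervals (e.g. SINEs) are annotated onto
  hits.
* **Knockout feasibility** — `spliceSiteUsage` checks, per transcript,
  whether the circRNA's SA or SD coincides with an internal splice
  boundary; verdict `SA_MUTABLE` means an AG→TC acceptor edit depletes
  the circle without touching any protected (coding) transcript.
* **Cryptic acceptor prediction** — `crypticAcceptorScan` finds the
  first 5′-AG-3′ downstream of a destroyed acceptor and returns the
  shifted circle definition and lost exon prefix.
* **RFLP genotyping** — `rflpDigest`/`rflpCompare` predict restriction
  fragments per allele (Dde I `C^TNAG` by default) and whether a digest
  discriminates the genotypes.
* **Junction-centric design** — `buildCircle`, `designJunctionShrna`
  (junction-spanning shRNAs with a hard substring selectivity guarantee
  against linear mRNAs), `checkDivergentPrimers` (circular vs linear
  amplicons), and `scanSeedSites` (canonical 6mer/7mer-A1/7mer-m8/8mer
  miRNA seed sites with wrap-around handling).
* **Circular ORFs and PRM targets** — `findCircularOrfs` translates
  across the junction (terminated and rolling ORFs), `trypsinDigest` /
  `discriminativePeptides` select tryptic peptides unique to the
  circle-encoded product, and `monoisotopicMass` / `peptideMz` /
  `feasibleCharges` compute exact monoisotopic PRM inclusion masses,
  `m/z = (M + z·1.007276)/z`.
* **qPCR quantification** — `relativeExpression` implements
  2^(−ΔCt) against the mean of two housekeepers with
  reference-condition rescaling; `circLinearRatio` flags conditions in
  which the circle is the main transcriptional output.
* **Synthetic loci** — `syntheticLocusSpec` / `makeLocus` generate
  deterministic ground-truthed fixtures (planted RCMs at exact
  identities, planted cryptic AG, multi-transcript recipes), and
  `makeMimicLocus` bundles a full showcase locus; `runPipeline` ties
  all stages together.

## Worked example

```r
library(circlocus)

bundle <- makeMimicLocus()          # deterministic multi-transcript locus
usage  <- spliceSiteUsage(bundleLocus(bundle), bundleCirc(bundle))
usage$verdict
#> [1] "SA_MUTABLE"
usage$table[, 1:4]
#>   transcript_id uses_SA uses_SD overlap_class
#> 1            T1   FALSE    TRUE        exonic
#> 2            T2   FALSE    TRUE        exonic
#> 3            T3    TRUE   FALSE        exonic
#> 4            T4    TRUE   FALSE        exonic
#> 5            T5   FALSE   FALSE      intronic
#> 6            T6   FALSE   FALSE      intronic
```

Only two minor non-coding transcripts use the circle's acceptor, so an
AG→TC edit of the SA knocks out the circRNA specifically.

```r
fl   <- flankingIntrons(bundleGenome(bundle), bundleCirc(bundle),
                        bundle@extras$introns)
hits <- findRCM(fl$up, fl$down, rcmParams(sensitive = TRUE))
rankCandidates(hits, 3)[, c("up_start", "up_end", "down_start",
                            "down_end", "length", "identity", "score")]
#>   up_start up_end down_start down_end length  identity score
#> 1       51    270         61      280    220 0.9500000   176
#> 2      349    540        361      552    192 0.9479167   152
#> 3      651    810        661      820    160 0.9187500   108
```

The top-ranked RCMs recover the longest planted inverted repeats of the
flanking introns at their planted identities.

```r
circle <- buildCircle(bundleGenome(bundle), bundleCirc(bundle))
orfs   <- findCircularOrfs(circle)
best   <- orfs[orfs$spans_junction & orfs$classification == "terminated", ]
best   <- best[which.max(best$aa_length), ]
best[, c("start", "aa_length", "spans_junction", "laps")]
#>    start aa_length spans_junction laps
#> 13   488        95           TRUE    1

prm <- prmTargets(best$peptide, bundle@extras$linear_protein)
subset(prm, peptide %in% c("NLRGHNSESCK", "GHNSESCK", "SPSRTFQS"))
#>        peptide missed neutral_mass charge        mz
#> 1  NLRGHNSESCK      1    1243.5728      1 1244.5800
#> 2  NLRGHNSESCK      1    1243.5728      2  622.7937
#> 3  NLRGHNSESCK      1    1243.5728      3  415.5315
#> 4     GHNSESCK      0     860.3447      1  861.3519
#> 5     GHNSESCK      0     860.3447      2  431.1796
#> 9     SPSRTFQS      1     908.4352      1  909.4425
#> 10    SPSRTFQS      1     908.4352      2  455.2249
```

The circle encodes a 95-aa ORF across the backsplice junction sharing
its first 84 residues with the linear protein; the discriminative
tryptic peptides and their scan-feasible charge states form the PRM
inclusion list (m/z reported to five decimals, unmodified cysteine).

See `vignettes/circlocus-methods.Rmd` for the models, parameter
conventions and known limitations.

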