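---
title: "Calling recurrent methylation changes and linking them to expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling recurrent methylation changes and linking them to expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`dmrlink` implements the comparative methylome analysis used to
characterize tumor cohorts profiled by whole-genome bisulfite sequencing
(WGBS) against a panel of normal controls, and to connect recurrent
promoter methylation changes to gene expression changes. The design follows
the situation typical of rare-tumor studies: a handful of tumors, each
compared individually against one averaged control profile, with
recurrence across tumors doing the work that replication would otherwise
do.

The stages are:

1. **Control profile.** Per CpG, the unweighted mean of the per-control
   methylation percents over all controls covering the site at \(\ge 5\times\)
   (`buildControlProfile()`). The mean of percents — not a pooled-count
   estimate — keeps each control's weight equal regardless of its depth.
   By default a CpG must be covered in *all* controls to enter the profile;
   this is the stricter of the two readings of "overlapping in all samples"
   and is exposed as `requireAll`.
2. **DMCs.** A CpG is a differentially methylated cytosine when the tumor's
   methylation percent differs from the control mean by at least 10
   percentage points (`classifyCpgs()`, `callDmcs()`). The boundary is
   inclusive ("at least 10%"). No per-site significance test is applied by
   default: with one tumor against five control values, a rank test cannot
   reach p < 0.05 at a single site (the best achievable two-sided p is
   1/3), so the significance criterion belongs to the region level. An
   optional per-site Fisher exact test of tumor counts against pooled
   control counts is available behind `siteTest = "proportion"`.
3. **DMRs.** Maximal runs of at least 3 same-direction DMCs, each adjacent
   pair at most 100 bp apart (`segmentDmrs()`), tested with a
   Mann–Whitney U over the member CpGs: tumor per-CpG percents versus
   control mean per-CpG percents (`testDmr()`). The test is one-sided in
   the run's direction with an inclusive p \(\le\) 0.05 threshold. This
   choice is forced by the region definition itself: a 3-CpG region with
   complete separation has exact one-sided p = 1/C(6,3) = 0.05, so a
   two-sided or exclusive threshold would make the stated minimum region
   size uncallable. Both sidedness and threshold are arguments. For group
   sizes up to 8 per side the exact permutation distribution over all
   C(2k, k) assignments of the observed (possibly tied) values is
   enumerated; larger regions use the normal approximation with midranks,
   tie-corrected variance and continuity correction. No multiple-testing
   correction is applied by default (region counts are descriptive, and
   raw p < 0.05 matches the upstream definition); Benjamini–Hochberg is
   available behind `bhCorrect`.
4. **Annotation.** Features receive every element class they overlap by at
   least 1 bp — classes are deliberately non-exclusive, matching
   bedtools-intersect semantics, so a DMR in a promoter-embedded repeat
   counts for both. An exclusive priority mode (promoter > exon > intron >
   gene body > enhancer > repeat > intergenic) exists for
   distribution-style summaries, since published element-distribution pies
   are ambiguous about multi-label handling. Promoters span −1500 bp to
   +500 bp around the TSS, strand-relative, with the TSS base itself as the
   first downstream base; coordinates are 1-based inclusive internally
   (the native convention of cytosine reports) and converted to 0-based
   half-open only at the BED boundary.
5. **Recurrence.** Same-direction DMRs from different tumors are clustered
   by single-linkage 1-bp overlap; a cluster supported by all tumors is one
   merged core-signature region (`recurrentDmrs()`). The merged-region
   reading is the only one that yields a single per-direction count; a
   reciprocal-overlap flag is provided since the identity rule across
   samples is not standardized.
6. **Expression.** FPKM from counts and lengths, per-tumor fold change
   (tumor + ε)/(control mean + ε) with ε = 0.1 (prevents division by zero
   while negligible at FPKM ≥ 1), and a per-gene, per-tumor significance
   contract (FC, p). The built-in test is a z-score of the tumor's
   log2(FPKM + ε) against the control replicate distribution — an explicit
   screening approximation for the one-tumor-versus-panel design, not a
   count-model fit. An externally produced differential-expression table
   can be imported instead; fold changes are always recomputed from FPKM so
   the two modes agree on FC.
7. **Integration.** A gene is `hypo_up` when its promoter carries a
   hypomethylated DMR in at least 6 of 7 tumors and its expression is up
   (FC ≥ 2, p < 0.05 by default) in a majority of expression-profiled
   tumors; `hyper_down` symmetrically. The methylation-recurrence and
   expression-recurrence knobs are independent because published analyses
   combine them at different strengths; `integrationProfile()` bundles the
   two conventional settings (`"fig5a"`: FC ≥ 2; `"text25"`: FC ≥ 1.5).
8. **Lethality screen.** A plain inclusive threshold (≤ −1) on a supplied
   gene-effect matrix, tabulated by lineage, with a common-essential flag
   at 90% of lines. The matrix semantics are the caller's responsibility.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `minCoverage` | 5 | reads | minimum CpG depth for any percent to be trusted |
| `deltaThreshold` | 10 | percentage points | DMC definition, inclusive |
| `minCpgs` | 3 | CpGs | minimum run length for a DMR |
| `maxGap` | 100 | bp | maximum distance between consecutive member DMCs |
| `alpha` | 0.05 | — | region-level Mann–Whitney threshold, inclusive |
| `upstream`/`downstream` | 1500/500 | bp | promoter window around the TSS |
| `pseudocount` | 0.1 | FPKM | fold-change stabilizer |
| `fcThreshold` | 2 (or 1.5) | fold | expression-change cutoff for integration |
| `methMinTumors` | 6 (of 7) | tumors | promoter-DMR recurrence for integration |
| `fpkmThreshold` | 5 | FPKM | highly-expressed gene list |
| `effectThreshold` | −1 | score | lethality cutoff, inclusive |

Strand merging of symmetric CpG pairs is on by default: whether calls
should be merged before the coverage filter is not documented for the
original processing, merging is standard practice and roughly doubles
per-site coverage, and the flag (`mergeStrands`) preserves the other
reading.

## What the synthetic generator emulates

`simConfig()`/`simulateStudy()` generate a complete miniature study with
recorded ground truth:

* **Genome and annotation** — 2 chromosomes × 750 kb, 150 gene models with
  strand-mixed TSS, exons/introns, one enhancer per gene slot, and random
  repeats covering 20% of the genome.
* **Methylome** — background CpGs at a mean spacing of 100 bp plus dense
  promoter islands (30 bp); latent per-CpG methylation from a
  two-component Beta mixture (70% Beta(8,1) high mode, 30% Beta(1,8) low
  mode), giving the strongly bimodal genome-wide distribution in which
  most CpGs are highly methylated. Per-sample, per-CpG logit-normal jitter
  (σ = 0.3) makes replicate controls correlate strongly but imperfectly
  (genome-wide CpG Pearson R ≈ 0.95–0.97). Real replicate correlations are
  lower (≈ 0.73–0.85) because real noise is locally co-methylated and
  overdispersed; since adjacent simulated CpGs are conditionally
  independent, matching that range would require jitter so large it would
  contradict the differential-calling behavior the generator exists to
  exercise. Coverage is Poisson(30) floored at 5; observed counts are
  Binomial(coverage, level).
* **Planted DMRs** — blocks of a chosen direction, magnitude (±30 to ±40
  points), CpG count and element class, with per-tumor presence patterns
  (`"all"`, `"6of7"`, explicit masks) so every recurrence threshold can be
  exercised directly. Planted blocks are laid at 40-bp CpG spacing inside
  their target element: region callers can only detect DMRs where CpG
  density permits three DMCs within the gap limit, so planting signal in
  CpG-sparse territory would simulate a signal the method is not defined
  over. Block baselines are drawn so the shifted level stays inside
  [0, 100].
* **Expression** — log-normal baseline means, negative-binomial counts at
  dispersion 0.1 with 4 control replicates, planted universal up/down
  genes, and *coupled* genes: genes carrying a planted promoter block
  whose fold change (4× up for hypo, 4× down for hyper) is applied exactly
  in the tumors where the block is present. Planted and coupled fold
  changes are placed on genes with baseline mean ≥ 50: coupling is a
  property of expressed genes, and near-silent genes cannot carry a
  measurable fold change. A noise-free mode emits exact expected
  abundances (as FPKM, no sampling) for limit checks.

What the generator does **not** emulate: read-level artifacts (bisulfite
conversion error, mapping bias), copy-number and purity effects,
co-methylation (adjacent CpGs are conditionally independent given the
latent level, whereas real neighbors are correlated — so the real
false-DMR rate at a given jitter is likely higher than the simulated one),
genome-scale CpG counts, and correlated expression programs. Passing tests
therefore demonstrate correctness of the computation and recoverability
under the declared noise model, not performance on real WGBS data.

## Numerical choices and degenerate inputs

* Bin edges for the 0–25/26–50/51–75/76–100 percent categories are
  interpreted on continuous means as [0,25], (25,50], (50,75], (75,100];
  a mean of exactly 25 falls in the lowest bin. The labels are
  integer-styled but promoter means are continuous, so the boundary had to
  be fixed one way; it is tested explicitly.
* Welch's unequal-variance t-test is the default for expression-by-bin
  comparisons (robustness; a pooled-variance flag restores the classical
  Student test). Bins with fewer than two genes yield NA comparisons, not
  errors.
* Fold change of 0/0 is defined as 1 via the pseudocount; "decreased
  2-fold" means FC ≤ 0.5 (symmetric thresholds).
* Empty inputs (no DMCs, no DMRs, empty BED) propagate as empty outputs,
  never errors; a tumor sharing no CpGs with the profile is an error.
* Promoter windows are clipped at position 1; chromosomes unknown to the
  annotation simply never intersect (no genome-build validation), which
  keeps the pipeline runnable on miniature genomes.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
studies: the default study is 2 × 750 kb with about 25,000 CpGs across 12
methylomes, 150 genes and 11 expression libraries; sensitivity and null
calibration use single-chromosome genomes of 100–500 kb. These sizes give
stable recovery estimates (50 planted regions, 20 coupled genes) while a
full run of every check completes in a few minutes; all stage code is
size-independent and has been structured to stream per chromosome.

## Known limitations

* The built-in expression test is a normal-tail screen; imported
  count-model results are preferred for inference-grade p-values.
* FPKM fold changes are sensitive to library composition: strongly
  asymmetric differential expression shifts all fold changes toward the
  null (no median-ratio normalization is applied, by design fidelity to
  the FPKM contract).
* Single-linkage 1-bp overlap can chain long recurrent regions across
  tumors; the reciprocal-overlap flag trades chaining for fragmentation.
* The exact Mann–Whitney path enumerates C(2k, k) assignments and is
  limited to 8 members per side; beyond that the corrected normal
  approximation is used.
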