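---
title: "Codon adaptation scoring and synonymous gene design: methods"
author: "codonrca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon adaptation scoring and synonymous gene design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonrca)
```

## The problem

Transgene expression in organisms with strongly biased, GC-rich nuclear
genomes — red microalgae are the motivating case — depends heavily on how
well a coding sequence's synonymous-codon choices match the host's
preferences. This package implements the computational side of such an
expression study: choosing a reference set of highly expressed genes from
an RNA-seq count matrix, summarizing their codon usage, scoring candidate
gene versions against that usage, and designing new synonymous variants
with prescribed properties (fully optimized, rare-codon-enriched at fixed
GC, AT-rich, or fused to a secretion signal peptide).

## Reference-set selection

The input is a gene × sample matrix of read counts with per-gene CDS
lengths, sampled in replicate at several time points (the default design
is triplicates at 5, 7 and 9 hours of light, nine libraries in all).

1. **Normalization.** Per-sample size factors use the median-of-ratios
   scheme: every gene with positive counts in all samples contributes its
   cross-sample geometric mean as a reference, and a sample's factor is
   the median of count/reference over those genes. This is implemented
   directly (`size_factors_median_of_ratios()`), not delegated, because
   the formula *is* the specified computation; a unit test cross-checks
   it against an independent implementation of the same estimator.
2. **TPM.** `compute_tpm()` converts counts to length-normalized rates
   and rescales each sample to one million; every column sums to 1e6
   exactly.
3. **Stability filter.** Because the goal is constitutively high
   expression rather than time-point spikes, each gene gets a one-way
   ANOVA of log2(TPM+1) across time points (`stats::lm`/`anova`), and
   genes with Benjamini–Hochberg-adjusted p below `alpha` (default 0.05)
   are removed. The multiple-testing rule is a package choice — exposed
   as a parameter — since the convention is not fixed by the analysis it
   emulates. Genes with identical values in every sample get statistic 0
   and are always retained.
4. **Ranking.** Remaining genes are ordered by mean TPM over the pooled
   samples (all time points by default), descending; ties break
   lexicographically by identifier and are reported. Ranking by
   normalized counts instead of TPM is available via `use =
   "normalized"`; TPM is the default because the ranking should not
   favor long genes.

The top *k* (default 92) CDSs are tallied into a `codon_usage_table`:
counts, per-thousand usage, within-family synonymous fractions, and
nucleotide frequencies at codon positions 1–3. Stop codons are counted by
default, so a whole-CDS reference set of 81,120 nt yields exactly 27,040
codons; a flag excludes them.

## CAI and RCA

For codon *c* with reference-set frequency *f(c)*:

* **CAI** relative adaptiveness: `w(c) = f(c) / max f` over *c*'s
  synonymous family.
* **RCA**: each frequency is first divided by the product of positional
  backgrounds, `RCA(xyz) = f(xyz) / (f1(x) f2(y) f3(z))`, then normalized
  within the family. RCA therefore separates codon preference proper from
  what overall nucleotide composition (e.g. GC richness) already
  explains, which is why it is the default for GC-rich hosts.

A gene's score is the geometric mean of its non-stop codons' *w*, times
100, with the minimum *w* reported alongside; GC and GC3 are computed on
the full CDS. The geometric mean is the default because it is the
convention of the CAI/RCA index family (a single unusable codon should
drag the score hard); the arithmetic mean is available via `mean_kind`
for comparisons. The printed values the index family reports could not
be used to fix the convention empirically — the underlying supplementary
sequences are not shipped — so the tradition's default stands.

**Numerical choices.** Zero-count codons receive a pseudocount (default
0.5) before frequencies are formed, and the positional backgrounds are
recomputed from the adjusted counts; this keeps the two indices exactly
equal on tables with uniform backgrounds and prevents zero *w* from
annihilating geometric means. With `pseudocount = 0`, families wholly
absent from the reference get `NA` adaptiveness and scoring a gene that
uses them is an error rather than a silent zero. Single-codon families
(Met, Trp) always have *w* = 1. Stops are excluded from gene scores.

## Variant design

* `optimize_max()` encodes every residue with its family's maximal-*w*
  codon; ties break to the lexicographically smallest codon and the stop
  is the table's most frequent one, so designs are reproducible
  byte-for-byte. The result scores average = minimum = 100 by
  construction.
* `deoptimize_fixed_gc()` minimizes Σ log *w* over all synonymous
  recodings subject to the total G+C count lying in an integer window
  around a target. The optimum is exact: a dynamic program over (codon
  position, cumulative G+C count). The percentage-point tolerance is
  floored/ceiled into whole-base bounds, so feasibility never flaps on
  floating point; infeasible windows report the achievable GC range.
  This generalizes the G↔C-swap-style designs of low-adaptation,
  host-like-GC gene versions: the optimizer is deliberately not
  restricted to literal G-to-C substitutions, which are merely the
  dominant moves it finds. The objective is geometric-mean-consistent;
  an arithmetic variant exists for parity with scoring.
* `design_at_rich()` picks the minimal-G+C codon per family (ties to the
  rarest codon under the table), giving the provably minimal GC over all
  synonymous encodings — the chloroplast-style AT-rich version.
* `build_secretion_variant()` fuses a codon-optimized signal peptide
  (e.g. the 21-residue signal peptide of a secreted carbonic anhydrase)
  to a mature CDS, optionally dropping the mature initiator Met and
  optionally inserting table-optimal HDEL codons before the stop for ER
  retention. Whether the initiator Met should be kept after the signal
  peptide is genuinely open (incomplete signal-peptidase cleavage makes
  either convention defensible), so both are supported and neither is
  asserted as the canonical one. The mature CDS's own stop codon is
  retained.

All strategies preserve the encoded protein exactly; this is asserted
across randomized inputs in the test suite.

## The synthetic-data generator

`synthetic_spec()` fixes the study conditions; all randomness hangs off
one seed with per-operation derived streams, so every artifact replays.

* **Codon usage.** Within-family probabilities are symmetric
  Dirichlet(0.5) draws — strong, irregular bias, the regime the scoring
  indices are designed for.
* **Reference CDSs.** ATG + uniform-amino-acid codons drawn from the
  usage + a stop; default lengths 150–450 codons (mean ≈ 300, i.e.
  ~900-nt CDSs, so 92 genes carry ≈ 27,000 codons). `bias_coupling`
  optionally shrinks lowly expressed genes' bias toward uniform,
  emulating selection-driven codon usage.
* **Counts.** Gene means are expression × length × sample depth
  (log-normal expression, sd 1.5 on the log scale, so a small set of
  genes dominates as in real transcriptomes), drawn negative-binomially
  with dispersion 0.05; ten genes receive an 8-fold effect at one time
  point, which the stability filter is expected to catch. TPM rank
  equals expression rank by construction, so ranking has a known ground
  truth.

What passing tests on this generator do **not** show about real data:
real transcriptomes have non-uniform amino-acid composition, correlated
codon usage between genes, length-dependent coverage biases, and
mapping/counting artifacts; none of these are simulated. The generator
validates the *arithmetic* of the pipeline and its statistical behavior
under known truth, not robustness to real-world measurement error.

**Sampling limits.** At ~27,000 codons a family's synonymous fraction
carries multinomial noise of se ≈ 0.014 (uniform amino-acid marginal,
~1,300 codons per family), and the within-family ratio *w* roughly
doubles that for near-tied codons. Recovery of ground-truth fractions is
therefore accurate to ±0.03 only in typical families, and the worst
single *w* across a table can deviate by ~0.1 at this depth. The tests
assert the quantile version (≥90% of *w* within 0.05, all within 0.2)
and, separately, that optimal-codon choices under the recovered and true
tables agree on ≥95% of families — the decision-relevant quantity.

## The synthetic five-variant study

`synthetic_variant_study()` reproduces the structure of a classical
transgene-design comparison without any external sequences: one
239-residue reporter protein; a GC3-rich host usage (Dirichlet shape
tripled for G/C-ending codons, emulating a GC-rich nuclear genome); and
five synonymous versions — AT-rich, GC-matched/rare-codon (exact DP),
optimized for a distantly related usage (Dirichlet concentration 2
around the host), optimized for a closely related usage (concentration
200, emulating a donor genome whose codon usage is similar enough that
the design retains no rare codons), and host-optimized. The
concentrations were fixed by design-time simulation of those qualitative
conditions before any acceptance checks were run. Scored against the
host table, the expected ordering AT-rich < distant < similar ≤ host
(= 100) emerges from the construction, not from tuned scores. All
sequences in this study are synthetic and are documented as such.

## Problem sizes and defaults

The shipped tests and the acceptance script run on deliberately compact
instances — tables of 27,040 codons, matrices of 40–150 genes × 9
samples, DP oracles on ≤6-codon inputs over 50 random tables — chosen so
the whole validation suite completes in well under a minute while still
exercising every code path at realistic codon depths. Larger inputs
change nothing structurally: the DP is O(L² · family size) in sequence
length and all other stages are linear.

## Known limitations

* RCA requires global codon frequencies; usage tables that carry only
  within-family fractions support CAI scoring only.
* The stability filter assumes a balanced one-way layout (≥2 replicates
  per time point) and equal-variance ANOVA; unbalanced or heteroscedastic
  designs are not special-cased.
* The deoptimizer's GC window binds the whole CDS including the stop
  codon; local (windowed) GC control is out of scope.
* No restriction-site, homopolymer or mRNA-structure avoidance is
  applied to designs.
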