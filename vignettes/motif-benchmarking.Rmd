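---
title: "Benchmarking TF binding models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking TF binding models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifbench)
```

## The problem

Computational models of transcription factor (TF) binding specificity —
from classic position weight matrices (PWMs) to arbitrary machine-learning
scorers — are only comparable when they are evaluated on the same held-out
data, with the same metrics, and with negative (unbound) sets that control
for the obvious confounders: GC composition, local genomic context, and
read identity between training and test material. `motifbench` implements
such an evaluation framework end to end: dataset construction from five
experimental platform types (ChIP-Seq peaks, genomic HT-SELEX peaks,
HT-SELEX reads, SMiLE-Seq reads, and protein-binding microarrays),
PWM scanning, multi-metric evaluation, hierarchical rank aggregation, and
a concordance analysis of allele-specific binding predictions. A synthetic
data generator with planted motifs makes every stage testable without any
external download.

## Position matrices and scanning

A position frequency matrix (PFM) is a width × 4 table of per-position
base probabilities (accepted widths 5–30; count matrices are normalized at
parse time). Before scoring, three derived forms are computed by
`to_scoring_matrices()`:

* the **pseudocounted PFM**: `p + 1e-5` entrywise, with no
  renormalization;
* the **PWM**: `log2((p + 1e-5) / 0.25)`, the log-odds against a uniform
  background, so every weight lies in
  `[log2(4e-5), log2(4.00004)] ≈ [-14.6096, 2.0000]`;
* the **integer weight matrix**: each weight truncated to five decimals
  and scaled by `1e5`. Floating-point weights drive the scanners; the
  integer grid is the exact lattice on which score distributions and
  P-values are computed, so the two never disagree about what "the same
  score" means.

Two scanning modes are provided. The **best-hit** score is the maximum
additive PWM score over all windows and both strands; ties resolve to the
lowest offset, `+` strand first, so scans are reproducible. The
**sum-occupancy** score is the sum over all windows and strands of the
window's emission probability under the pseudocounted PFM — a
total-binding proxy that rewards multiple or overlapping sites. Occupancy
uses probabilities directly (no odds ratio, no length normalization): it
is therefore monotone under sequence extension, which the tests assert.
`N` bases contribute probability 0.25 and weight 0, neutral under the
uniform background. For reads from in-vitro selection libraries, 20 bp of
the constant flanking sequence is attached on each side before scanning
(`score_with_flanks()`), so binding sites overhanging the variable insert
are scorable; the same flanks are attached for both classes, so they
cannot separate positives from negatives by themselves. Flanks are
attached for both HT-SELEX and SMiLE-Seq scoring.

## Benchmark dataset construction

All coordinates are 0-based and half-open internally; conversion happens
only at file boundaries.

**Genomic platforms (CHS, GHTS).** Positives are 301-bp windows centered
on the summits of reproducible peaks (peaks whose window would cross a
chromosome end are dropped, keeping widths exact). Three negative kinds
are built per TF:

* *shades* — one 300-bp region per peak at a uniform-random 300–600 bp gap
  from the (≥300 bp, symmetrically extended) peak border, on a random
  side; candidates overlapping any peak or closer than 300 bp to any
  positive are re-drawn up to 100 times and then dropped. Shades share
  local context with positives and are balanced 1:1.
* *aliens* — 301-bp windows on the summits of another TF's peaks,
  GC-matched, 1:2.
* *random* — random genomic windows, GC-matched, 1:2.

Train/test splits are whole-chromosome holdouts: odd autosomes train,
even autosomes test, sex chromosomes excluded.

**Read platforms (HTS, SMS).** Reads are deduplicated within each cycle;
reads occurring in two or more cycles, or in another TF's pools, are
removed everywhere (they cannot be attributed unambiguously). Positives
are an equal-per-cycle sample (each cycle contributes
`min(100000, smallest cycle)` reads by default). Negatives come from the
input (zero-cycle) library or from alien reads, are GC-matched,
sequence-disjoint from positives, and sized 1:2 (HTS) or 1:5 (SMS).

**PBM.** Two normalizations: *SD* (log10 intensity minus the median of
the probe's 11×11 grid window, truncated at edges — the median is robust
to bright outlier spots) and *QNZS* (log10, quantile normalization across
arrays, then a per-probe Z-score with mean and sd taken across the whole
array pool). Positives are probes above `mean + 4·sd` (SD) or `Z > 4`
(QNZS), with a minimum of the top 50 probes when fewer pass; ties break by
value then probe id. Negatives are a GC-matched 1:10 sample of the rest.

**GC matching.** `gc_match_sample()` bins sequences by GC fraction
(width 0.05), allocates per-bin sample sizes proportional to the
reference distribution (largest-remainder rounding), and borrows deficits
from the nearest non-exhausted bins with a warning. Binning is the
simplest auditable scheme that makes the matched-distribution contract
checkable (the tests assert per-bin agreement and a small chi-square
distance).

## Metrics

* **AUROC** — the probability that a random positive outscores a random
  negative, ties counting one half (computed through the rank-sum
  identity; equals the trapezoidal ROC area and the normalized
  Mann–Whitney U).
* **AUPRC** — the continuous Davis–Goadrich interpolation: between
  adjacent score thresholds the false-positive count is linear in the
  true-positive count and the precision integral has a closed form.
  Estimator families differ in the third digit at small n, so tests
  compare against a fine numeric integration oracle at tolerance 1e-3.
* **mean top-fraction scores** — for fractions 1, 0.5, 0.25 the top
  `ceiling(f·n)` positives and negatives are selected independently by
  score and AUROC/AUPRC recomputed; the mean over fractions focuses the
  comparison on the high-affinity end of single-round selection assays.
* **τ_b** — Kendall rank correlation with tie correction between model
  scores and SELEX cycle numbers, computed on the positive reads (the
  regression task is predicting the cycle that yielded a read; negatives
  carry no cycle). Per-replicate values are averaged by the caller.
* **log2-odds normalization** — `log2(m/(1-m)) - log2(r/(1-r))` compares
  a bounded metric against a reference model's value on the same data;
  the odds reading (rather than a plain ratio) keeps the score
  antisymmetric, and clamping to `[1e-6, 1-1e-6]` keeps it finite at the
  bounds.

## Hierarchical ranking

Within each (platform, TF, benchmark) cell — a benchmark being one
negative-set kind × metric pair — submissions are ranked with averaged
ties. Ranks are combined with the log-normalized score
`sum(-log(r/(N+1)))` across a platform's benchmarks, re-ranked per
(platform, TF); each team's best submission is re-ranked per cell; and
the team-level cell ranks are combined with the same transform into the
overall order. The natural log is used — the base rescales scores and
cannot change any ordering. Missing submissions receive the lowest
possible rank (`N`) wherever they are absent; fractional (tied) ranks
feed the log formula directly, preserving symmetry among tied teams.
Level-4 aggregation weighs every (platform, TF) cell equally.
`stability_analysis()` repeats the aggregation over subsamples that drop
each (TF, platform) cell with probability 0.25 (1000 replicates by
default, retaining 75% of the pool on average) and reports per-team rank
frequencies.

## Allelic (rSNP) evaluation

For a variant with a 301-bp centered context, each allele's best-hit
score is taken over both strands among the windows overlapping the
variant position only — whole-region scores would dilute the allele
contrast — and converted to an exact P-value under the uniform background.
The P-value comes from the full distribution of the word score on the
integer weight grid, built by position-wise convolution over distinct
achievable scores; thresholds map to the grid by flooring, making the DP
exact on-grid (tests compare against full word enumeration for widths
≤ 8). For wide matrices the distinct-sum count approaches `4^width`, so
above `4^12` states the grid is coarsened by powers of ten — a
deterministic, documented approximation that the bundled analyses never
trigger. External (non-PWM) models supply per-allele scores instead.

The predicted preference follows the sign of `log10(p_alt/p_ref)`;
variants are sorted by `-log10(min(p_ref, p_alt))` and the concordance
curve plots the concordant fraction of the top k against k/n. Ties in the
predicted preference count one half, and the x-axis is normalized to
(0, 1] before trapezoidal integration — together these give a statistic
bounded in [0, 1] with expectation 0.5 under random predictions and 1 for
perfect ones, which the acceptance checks verify by simulation. Per-TF
AUCs aggregate by a variant-count-weighted mean.

## The synthetic data generator

The generator emulates the *structure* the benchmarks assume, not the
biophysics of any particular TF:

* **Motifs** are Dirichlet draws (default width 8, concentration 0.2 — a
  sharp, information-rich motif of typical core-site width).
* **Backgrounds** are i.i.d. with GC 0.41 (the human genome average);
  SELEX libraries use GC 0.5 (unbiased synthesis).
* **SELEX enrichment**: the reads of cycle c are a multinomial sample
  from a fresh library draw weighted by `occupancy^(stringency·c)`.
  Selection acting cumulatively on affinity produces monotone enrichment
  and a positive score–cycle correlation while keeping reads distinct
  across cycles, as the sequenced samples of a huge molecular pool are;
  sequentially resampling a small finite pool would instead make later
  cycles near-copies of earlier ones and collide with the deduplication
  rules at desk scale. The default stringency 0.3 is a soft tilt chosen
  so that enrichment stays progressive over several cycles rather than
  saturating after the first selection round; it is a qualitative
  emulation, not a biophysical claim.
* **Genomic experiments** plant motif words at well-separated loci on a
  toy multi-chromosome genome and emit peaks with summits at the planted
  centers; optionally a second motif's loci provide alien peaks.
  Variants sit inside planted words; the observed allelic preference is
  the sign of the best-hit score change between alleles, flipped with
  probability 0.05 (standing in for read-count-derived allelic imbalance,
  which is out of scope).
* **PBM arrays**: probe intensity is `1 + 5000·occupancy` (about three
  orders of magnitude of dynamic range) seen through a shared per-probe
  background effect (sequence-dependent optical bias), a per-array
  log-additive spatial gradient, and lognormal noise. The normalization
  pool contains 150 arrays by default, of which two are target
  replicates; the others bind their own probe sets, drawn outside the
  target's high-affinity tail, at matched strengths. The pool size
  matters: a per-probe Z-score that includes the target arrays in its
  mean and sd is bounded near `(n-1)/sqrt(n)`, so small pools can never
  reach threshold-level Z values — mirroring why the real normalization
  pools arrays across many experiments.

What the generator does **not** emulate: chromatin context, PCR and
sequencing error, optical saturation, probe secondary structure, motif
subtypes, or dinucleotide background structure. Passing tests therefore
demonstrate that the pipeline's bookkeeping, controls, and statistics
behave as specified — not that any particular model will excel on real
data.

## Problem sizes and runtime choices

The bundled suites use desk-scale sizes chosen to keep the full synthetic
run fast while leaving clear statistical margins: a 4 × 200 kb genome
with 60 target and 180 alien sites (about 30 test-chromosome positives
per genomic dataset), 300 positives per SELEX cycle from 2000-read pools,
1600 PBM probes on a 40 × 40 grid, and 30 variants per TF. Sampler seeds
are explicit arguments everywhere; two runs with the same configuration
are identical, which the tests assert byte-for-byte on the metric tables.

## Known limitations

* The exact P-value DP is exponential in motif width in the worst case;
  widths above ~12 use the coarsened grid described above.
* `stats::cor(method = "kendall")` computes τ_b in O(n²); read sets per
  replicate should stay in the tens of thousands.
* GC borrowing degrades matching quality when the candidate pool is far
  from the reference distribution; the warning reports how many draws
  were borrowed.
* The AUPRC estimator is one member of the continuous-interpolation
  family; third-digit differences against other estimators are expected
  and covered by the test tolerance.
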