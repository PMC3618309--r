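---
title: "Population-scale CNV discovery from SNP-array signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-scale CNV discovery from SNP-array signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpopscan)
```

## Overview

`cnvpopscan` implements a population-scale copy-number-variant (CNV)
screening pipeline for SNP genotyping array data of the BovineSNP50 class:
per-probe Log R Ratio (LRR, the log2 ratio of observed to expected total
intensity, ~0 at the diploid state) and B allele frequency (BAF, the
fraction of signal attributable to the B allele, clustering at {0, 1/2, 1}
for diploid genotypes). The pipeline stages are

1. cohort simulation (`cohort_spec()`, `simulate_cohort()`),
2. sample QC and GC-wave correction (`assess_sample()`, `gc_correct()`),
3. HMM segmentation with per-call Bayes factors, run under two presets
   (`call_cohort()`, `hmm_params()`),
4. dual-track consensus, 8 Mb filter and Bayes-factor threshold
   (`merge_dual_calls()`, `filter_long_calls()`, `apply_bf_threshold()`),
5. CNV-region construction and classification (`build_cnvrs()`),
6. segmental-duplication colocalization by permutation
   (`sd_association()`),
7. gene annotation (`annotate_intervals()`, `biotype_tally()`),
8. breed summaries and rank-sum comparisons (`breed_summaries()`,
   `compare_breeds()`),
9. qPCR delta-delta-Ct validation (`delta_delta_ct()`,
   `regress_validation()`, `bf_sweep()`).

The numbered scripts under `analysis/` drive the stages over generated
data; every computation lives in the package and is exercised by the test
suite. Coordinates are 1-based inclusive everywhere; BED input is converted
at the boundary. Only autosomes (1–29 for cattle) are analysed; records on
other chromosomes are skipped with a logged count. Missing BAF values are
`NA` and contribute nothing to any likelihood.

## The synthetic cohort

Real population-scale genotype data (thousands of animals) cannot ship with
a package, so the generator is a first-class module that emulates the
statistical structure the downstream analyses assume. The defaults are the
desk-scale study conditions used throughout the tests and the acceptance
script, chosen once:

* **Genome and probes.** Two autosomes of 50 Mb, inter-probe gaps i.i.d.
  exponential with mean 49 kb — the BovineSNP50 density — giving
  Poisson-level variation in probe counts and realistic gap variance. The
  GC fraction is a smooth AR(1) track (lag-1 correlation 0.98) mapped into
  [0.3, 0.7].
* **Cohort.** 30 bulls in five breeds (10/8/5/4/3), proportional to the
  real panel's 891/705/482/369/207 split.
* **CNV loci.** 40 loci placed uniformly (chromosome probability
  proportional to placeable span). Lengths are log-normal with median
  700 kb and sigma `sqrt(2 log(930/700))` ≈ 0.754 so that the mean/median
  ratio matches the cohort's 930/700 kb. Every locus must cover ≥ 3 probes.
* **Frequency spectrum.** 90% of loci are singletons; the rest draw a
  carrier frequency from Beta(1, 19) (mean 5%) with at least two carriers.
  The published frequency spectrum is plotted but not tabulated, so the
  singleton mass is a modeling choice, not a measured value.
* **Copy-number classes.** Carrier copy numbers are multinomial with
  weights 92 : 5259 : 1592 : 550 for CN 0/1/3/4 — the cohort's class
  counts. Homozygous deletions are held to at most two carriers per locus
  (they are observed only at very low frequency in real populations,
  consistent with purifying selection); at loci with more carriers, CN 0
  draws are redrawn from the remaining classes. At the default spectrum
  this redraw affects a negligible fraction of calls.
* **Signals.** LRR at a probe in state *s* is Normal(mean_s + wave, 0.15)
  with means −3.0 / −0.66 / 0 / +0.40 / +0.68 for CN 0–4 — the de-facto
  SNP-array convention; the source data never state emission values, so
  they are configurable (`noise_spec()`). The wave term is
  `gc_wave_amplitude * (gc − mean gc)`. BAF draws a genotype cluster
  uniformly from the state's set (CN 2: {0, 1/2, 1}; CN 1: {0, 1}; CN 3:
  {0, 1/3, 2/3, 1}; CN 4: {0, 1/4, 1/2, 3/4, 1}; CN 0: uniform noise),
  perturbs it by Normal(0, 0.03) and clips to [0, 1]. Equal-weight cluster
  choice ignores allele-frequency structure; see Limitations.
* **SD track.** With enrichment *e* ≥ 1, a fraction 1 − 1/*e* of SD
  intervals is placed overlapping randomly chosen CNV loci, the rest
  uniformly; lengths log-normal with median 50 kb.
* **qPCR.** Target Ct = base − log2(CN/2) + Normal(0, ct_sd) per
  replicate; reference Ct = base + noise; triplicates independent. CN 0
  is censored at a 55-cycle ceiling (the protocol's cycle count).
  Amplification efficiency is exactly 2 per cycle by default and is a
  configuration knob.

What the generator deliberately omits: linkage disequilibrium, pedigree
and relatedness, X/Y chromosomes, raw intensity channels, batch and plate
effects, and allele-frequency-weighted genotype clusters. Passing tests
therefore demonstrate correctness of the analysis machinery under the
stated generative model, not performance on any real cohort.

## Sample QC and GC correction

The noise statistic is the per-sample LRR standard deviation with cutoff
0.30. The filter described for the real cohort reads "LogR ratio higher
than 0.30"; a mean LRR of 0.30 would indicate broken normalization rather
than noise, and 0.30 is the community-standard SD cutoff, so the SD
reading is adopted. The cutoff is a parameter (`lrr_sd_max`).

GC waves are removed per sample by OLS of LRR on centered GC fraction;
the corrected signal is the residual plus the original mean, so the
sample mean is preserved exactly and the corrected LRR is orthogonal to
GC (which also makes the correction idempotent). The GC window is
whatever the probe map's `gc_frac` encodes. Zero GC variance skips the
correction with a warning.

Calls longer than 8 Mb are removed (inclusive boundary: exactly 8 Mb is
kept), interpreting the length rule per call rather than per individual
so that per-sample statistics remain defined; dropping whole carriers
instead is a caller-side choice.

## The HMM caller and its Bayes factor

One five-state (CN 0–4) hidden Markov model stands in for the common
two-caller practice; re-implementing two published callers exactly is out
of scope, and running one engine under two presets reproduces the
analytically relevant property — two imperfectly concordant call tracks.
Preset A is tight (LRR sd 0.20, BAF sd 0.04, expected event length
500 kb, stay probability 0.95); preset B is wide (0.25 / 0.06 / 2 Mb /
0.90). State 0 gets a wide LRR sd (1.0/1.2) because homozygous-deletion
intensities are noisy.

*Emissions.* Gaussian LRR log-density plus the log of an equal-weight
Gaussian mixture over the state's BAF clusters; CN 0's BAF term is
uniform on [0, 1]; missing values contribute 0. Note the emission widths
are deliberately wider than the generator's noise (0.15): a caller does
not know the true noise, and the widths control the Bayes-factor scale
(below).

*Transitions.* Distance-aware: for inter-probe gap *d*, the stay
probability is `base * exp(−d/L) + pi_s * (1 − exp(−d/L))` with
off-diagonal mass proportional to the stationary weights
(0.005/0.05/0.89/0.04/0.015, favoring the diploid state); every row sums
to 1 at any distance, the chain approaches the stationary distribution as
*d* → ∞, and each chromosome restarts at the stationary distribution.

*Decoding.* Viterbi in log space, ties broken toward state 2 — exact,
reproducible boundaries, unlike posterior-marginal decoding. Maximal runs
of a constant non-diploid state become calls; runs under `min_probes = 3`
are dropped (the source analysis states no probe floor; 3 is the common
convention). On clean signals the decoder is verified against exhaustive
path enumeration.

*Bayes factor.* The per-call confidence is the log10 likelihood ratio,
over the call's probes only, of the constant called-state path versus the
constant diploid path, clipped below at zero. A restricted forward sum
over all paths visiting the called state was considered; the constant-path
ratio has the same contract (zero on diploid-modal data, monotone growth
with supporting probes at fixed noise, invariance to flanking data) and is
simpler to reason about and reproduce. With the preset emission widths, a
clean 10-probe heterozygous deletion at generator noise scores bf ≈ 15–30,
placing the conventional threshold sweep {10, 15, 20, 30} on a meaningful
scale. Both tracks share this scale, which is what makes "keep the call
with the higher BF" well-defined across tracks.

## Consensus, threshold and deduplication

Overlapping calls (same sample, same chromosome, ≥ 1 bp, same sign) from
the two tracks keep the higher-bf call; ties keep track A. Gains never
merge with losses. Non-overlapping calls from either track pass through:
the merge rule is only specified for co-detected events, and union
semantics maximizes sensitivity. The confidence threshold is inclusive
(bf ≥ 15 by default). Unique CNVs are exact (chrom, start, end, cn)
tuples — no reciprocal-overlap matching — with the highest-bf carrier as
representative and the carrier count as multiplicity.

The threshold itself is anchored by qPCR: `bf_sweep()` recomputes, at
each candidate threshold, the adjusted R² of qPCR copy number regressed
on array copy number over the assayed pairs (array CN is the cn of the
highest-bf surviving call overlapping the assayed region, else 2).
Spurious low-confidence calls depress the fit, so the R² flattening point
identifies the working threshold.

## CNV regions, coverage and summaries

CNVRs are connected components of the ≥ 1 bp-overlap graph (transitive
closure), the union-CNVR construction; mere adjacency (gap 0) does not
merge. Category is gain/loss if all members are on one side of 2, else
both. Frequencies use the post-QC cohort size; frequency classes use
strict inequality (> 1/2/5%). Genome coverage is the length of the union
of region envelopes over the summed autosome lengths.

Printed-style statistics round half-up: percentages to 2 decimals,
per-chromosome percentages to 1 decimal, ratios to 2 decimals
(`round_half_up()`; base R's banker's rounding would disagree with the
printed tables at exact halves). Every percentage field recomputes from
its own counts. The recurrence-spectrum bins are 1, 2, 3, 4–5, 6–10,
10–25, > 25 carriers; the printed bins "6-10" and "10-25" overlap at 10
and are disambiguated as 6–9 and 10–25 so that the counts partition.
"Breed-specific" means a unique-CNV key observed in no other breed.
Breed contrasts use the two-sided Wilcoxon-Mann-Whitney test: exact null
when min(n, m) ≤ 8 without ties, normal approximation with continuity
and tie correction otherwise; a degenerate pair (one constant value in
both groups) reports p = 1.

## SD colocalization test

The observed statistic is the fraction of unique CNVs sharing ≥ 1 bp with
any SD. Each of the 1000 permutations redraws all segments: length
resampled from the empirical CNV length distribution, chromosome
proportional to placeable span, start uniform so the segment fits;
permuted segments may overlap each other (no exclusion is imposed). The
p-value is the add-one estimator (1 + #{null ≥ observed})/(n_perm + 1),
which can never be zero; at 1000 permutations the resolution floor is
~0.001.

A practical note on calibration: the overlap *fraction* over *k* unique
CNVs takes values on a lattice of spacing 1/k. At desk scale (k ≈ 46)
ties between the observed and null fractions carry appreciable
probability mass, and because ties count toward the numerator the add-one
p-value is conservative — in repeated null cohorts the empirical
P(p < 0.05) falls somewhat below 0.05 (about 0.03 in the test suite's
400-cohort experiment) while never exceeding it. This is a property of
the discrete estimator at small k, disappears as the number of CNVs
grows, and does not affect power: at SD enrichment 4 the test reaches
p < 0.001 in effectively every replicate.

## qPCR validation

Copy number from Ct triplicates: dCt = mean target − mean reference;
ddCt = dCt(sample) − dCt(calibrator) with a diploid calibrator per
region; CN = 2 · 2^(−ddCt). The estimate is continuous — rounding to
integer states is the comparison's choice — and adding a constant to
every Ct leaves it unchanged. Efficiency is fixed at 2 by default
(efficiency was tested but not reported for the real assays) and
generalizes via the `amp_base` argument. Fully censored targets yield
CN 0. The validation regression is OLS of qPCR CN on array CN (that
orientation matches the published validation figure), reporting slope,
SE, two-sided t-test p and adjusted R².

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run entirely on generated data:
the default 2 × 50 Mb / 30-sample cohort (~2000 probes) for caller
recovery, 400 + 100 seeded cohorts for the permutation calibration and
power experiments, 200 seeded replicates of 50 assayed pairs for the
qPCR recovery check. These sizes make every experiment deterministic
under its seed and quick to re-run while leaving enough events (~50
truth calls per cohort) for the rates being estimated. All randomness
flows through explicit integer seeds; re-running any stage or the whole
`run_pipeline()` with the same seed is byte-identical.

## Known limitations

* The caller is one engine with two presets, not two independent
  algorithms; inter-caller disagreement is therefore milder than between
  genuinely different HMMs.
* Boundary precision is probe-limited; no sub-probe refinement is
  attempted, and call envelopes inherit probe positions.
* The Bayes factor is a constant-path likelihood ratio, not an
  objective-Bayes marginal; its absolute scale is calibrated by
  convention (10-probe heterozygous deletion ≈ 15–30), and only
  comparisons on a common scale are meaningful.
* Exact-coordinate deduplication under-merges nearly identical calls
  that differ by one probe; the published unique counts are cohort facts
  that depend on the original callers' boundary behavior and are not
  reproducible from summaries.
* The permutation test's add-one p-value is conservative for small
  numbers of CNVs (see above).
* The generator's BAF model draws genotype clusters with equal weights,
  ignoring population allele frequencies and Hardy-Weinberg structure;
  this slightly overweights informative heterozygous probes relative to
  real arrays.
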