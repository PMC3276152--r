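---
title: "Mapping replication-stress chromosome fragility from two-channel arrays"
author: "fragileMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping replication-stress chromosome fragility from two-channel arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When replication forks stall — for example under hydroxyurea in a
checkpoint-deficient yeast mutant — single-stranded DNA (ssDNA) accumulates
at the forks, and on recovery the chromosomes break preferentially where
those forks collapsed. Both signals can be labeled in gel (random-primed
labeling for ssDNA; end-repair incorporation for double-strand-break ends),
hybridized against a control channel on a genomic tiling microarray, and
read out as a per-probe fluorescence ratio along each chromosome. The
analytical questions are then: where along the genome is the signal
elevated, how reproducible and mutually similar are the resulting profiles,
and are the elevated positions closer to a given class of genomic feature
(late/inefficient "checked" replication origins versus early/efficient
"unchecked" ones) than chance placement on the array would predict?

fragileMap implements that analysis chain: ratio profiles with total-signal
normalization, fixed-window genomic Lowess smoothing, above-median site
calling and prominence-based peak calling, profile correlation, and a
randomization test for site/feature proximity — plus a synthetic two-channel
array simulator that lets every stage, including the statistical calibration
of the randomization test, be validated without hybridization data.

## The ratio profile model

For probe $i$ with experimental signal $E_i$, experimental background
$e_i$, control signal $C_i$ and control background $c_i$:

1. QC-flagged spots are removed outright.
2. Net signals $E_i - e_i$ and $C_i - c_i$ are formed; probes with
   non-positive net control signal cannot carry a ratio and are dropped
   (counted and logged, never imputed).
3. Each channel is divided by its genome-wide total, so both normalized
   channels sum to exactly 1 — this cancels any uniform scale difference
   between the channels (dye brightness, labeling efficiency, input mass).
4. The raw ratio is $r_i = \hat E_i / \hat C_i$, the normalized
   experimental over normalized control value.

Only total-signal normalization is applied: no spatial/print-tip
correction, no dye-swap averaging, no quantile normalization. The package
operates downstream of feature extraction and expects a per-probe table.

## Fixed-window Lowess smoothing

The smoothed value at probe $i$ is a locally weighted linear regression
over the probes within $\pm w/2$ of its midpoint on the same chromosome
(default window $w = 6000$ bp), with tricube weights
$(1 - (d/h)^3)^3$, $h = w/2$, on genomic distance $d$. Key choices:

* **Genomic span, not probe count.** The bandwidth is a fixed number of
  base pairs so it matches the 6 kb proximity cutoff used by the
  association test; the two parameters are deliberately the same quantity.
* **Degree 1, zero robustness iterations.** These are the canonical
  Cleveland local-linear defaults; they are recorded in the profile
  metadata. Degree-1 fitting reproduces any locally linear trend exactly,
  which the test suite asserts to 1e-9 and also cross-checks against an
  independent brute-force weighted-least-squares oracle at every probe.
* **Natural scale.** Ratios are smoothed and thresholded as ratios, not
  log-ratios, because sites are called on the plotted quantity.
* **Chromosome independence.** Windows never cross a chromosome boundary;
  a window containing a single probe returns the raw value with a warning.
* Degenerate windows (all covariate mass at one coordinate) fall back to
  the weighted mean.

Correlation between profiles is Pearson on smoothed values over the
intersection of probe ids (Spearman available via `method =`); profiles
with zero variance raise an error rather than returning `NA`.

## Site and peak calling

A **significant site** is a probe whose smoothed ratio is *strictly
greater* than the genome-wide median of the smoothed profile. The median
is genome-wide, not per-chromosome, because site counts are tallied into
single genome totals; the rule makes calls invariant to uniform rescaling
of the profile. Sites are probe-resolution points (probe midpoints), not
merged intervals. A constant profile yields an empty site set with a
warning, not an error.

**Peaks** are strict local maxima per chromosome filtered by topographic
prominence (height above the key saddle toward higher ground). The default
floor is half the interquartile range of the smoothed profile — a declared
convention of this package — with a small scale-relative epsilon guarding
the noiseless case where the IQR collapses to zero and numerical ripples
of order 1e-16 would otherwise qualify. Peak calling is used for
positive-control concordance (planted cut sites) and display, not for the
association counts.

## The randomization test

For each site, the distance to its nearest feature is measured **midpoint
to midpoint on the same chromosome** (features on other chromosomes are
infinitely far; an infinite distance is a valid value). The observed
statistic is the number of sites with a feature within the cutoff
(default 6000 bp, boundary **inclusive**). The null redraws an equal
number of positions uniformly **without replacement** from the unflagged
probe universe — distinct spots on the array — and recounts; with 10,000
draws the upper-tail p-value is the plain proportion
$p = \#\{\text{null} \ge \text{observed}\}/n_\text{sims}$, with ties
counted by the $\ge$ rule and no $+1$ smoothing (so $p = 1$ and small
exact fractions are both representable). Because the universe is fixed,
each probe's nearest-feature distance is computed once and a random
placement only samples the within-cutoff indicator; this is an exact
algebraic rewrite of the naive recomputation, and `exhaustiveNull()`
provides the fully enumerated placement distribution against which the
Monte Carlo path is verified on small instances.

The companion two-sample comparison of site fractions uses the Pearson
chi-square on the 2x2 table with Yates continuity correction
(`stats::prop.test`), statistic floored at zero and degenerate pooled
proportions returning $p = 1$.

No multiple-testing correction is applied across feature categories, and
only the upper tail is defined — enrichment, not depletion, is the
question being asked.

## The synthetic data generator

The simulator emulates a two-channel genomic hybridization:

* **Probe grid**: even tiling at a configurable spacing (290 bp emulates
  4x44K density on a 12 Mb genome; the test fixtures use 500 bp on a
  2 x 200 kb mini-genome so a full pipeline run takes well under a
  second), with a seeded random subset of spots flagged as anomalous.
* **Signal model**: the control channel has constant expectation; the
  experimental channel expectation is
  $\text{baseline} \times (1 + \sum_k A_k e^{-(x - \mu_k)^2 / 2\sigma_k^2})$
  at probe midpoint $x$ for gaussian peaks, while `point` peaks add their
  amplitude to the single covering probe (an idealized restriction-cut
  end label, and the shape behind the closed-form normalization identity
  $4N/(N+3)$ used in the tests).
* **Noise**: each channel is multiplied by independent log-normal noise
  with unit mean and coefficient of variation `noiseCv` — the standard
  two-channel fluorescence assumption, chosen because it leaves the
  expected log-ratio at zero, which the tests check analytically. A
  constant background is added to both channels and reported in the
  background columns, and flagged spots receive sub-background
  intensities.
* Seeds are explicit arguments everywhere; generation is bit-reproducible
  and no function touches global RNG state.

What the generator does **not** emulate: dye-swap asymmetries, print-tip
or other spatial artifacts, sequence-dependent hybridization efficiency,
repetitive elements that cross-hybridize (the Ty-element signals seen on
real arrays), or any mechanistic fork model — enrichment geometry is
purely descriptive. Passing tests therefore demonstrate the correctness
of the computational chain under a clean noise model, not robustness to
every artifact of real arrays.

### Study conditions used by the tests and the acceptance script

The planted-truth scenario places gaussian breakage enrichment (amplitude
6, width 2 kb, channel CV 0.1) at every "checked" origin (five per
chromosome at 30-150 kb) and none at the interleaved "unchecked" origins;
with 6 kb smoothing and cutoff and 10,000 randomizations, the expected
outcome is a vanishing checked-origin p-value and an unchecked-origin
p-value near 1 — since above-median calling concentrates calls in the peak
windows, non-peak regions (including unchecked-origin windows) are
*depleted* of calls relative to random placement. The null-calibration
fixture uses a 2000-probe universe with 500 sites and roughly half the
universe within the cutoff, sized so the within-cutoff null count
distribution is wide (SD about 7 counts) and the discrete permutation
p-value lattice is fine relative to the Kolmogorov-Smirnov critical value
at 500 replicates and alpha = 0.01.

## Degenerate inputs and numerical conventions

* Coordinates are BED-convention (0-based, half-open) in files; internal
  `GRanges` are 1-based; midpoints are real-valued (half-integral when
  derived from BED intervals) and distances are never rounded.
* Strand is ignored throughout; the assays are strand-agnostic.
* Empty feature set: observed count 0, all null counts 0, $p = 1$.
* More sites than unflagged probes: an error (the null is undefined).
* All probes dropped in ratio computation: an error; partial drops are
  logged counts.
* File parsers reject malformed rows with the offending line number;
  nothing is silently coerced.

## Limitations

* The exact smoothing and peak-identification conventions of the
  in-gel-labeling literature are under-specified; the defaults here
  (tricube, degree 1, prominence = IQR/2) are declared conventions,
  recorded in metadata, rather than re-derivations.
* Site counts are probe-resolution; a `--merge-within` style
  consolidation is deliberately not applied by default.
* The simulator's amplitudes are free parameters — real breakage
  enrichment magnitudes are only known relative to restriction-digest
  controls.
* Replicate profiles are correlated singly; no averaging before
  correlation.

## A worked run

```{r example}
library(fragileMap)
layout <- GenomeInfoDb::Seqinfo(c("chrA", "chrB"), c(200000L, 200000L))
probes <- makeProbeGrid(layout, spacing = 500, probeLength = 60)
checked <- FeatureSet(rep(c("chrA", "chrB"), each = 5),
                      rep(c(30000, 60000, 90000, 120000, 150000), 2),
                      "checked_origin", layout)
truth <- SyntheticTruth(peaks = data.frame(
  chrom = rep(c("chrA", "chrB"), each = 5),
  center = rep(c(30000, 60000, 90000, 120000, 150000), 2),
  amplitude = 6, width = 2000, shape = "gaussian"))
s <- simulateSample(probes, truth, noiseCv = 0.1, seed = 11)
prof <- lowessSmooth(computeRatios(s), windowBp = 6000)
sites <- callSignificantSites(prof)
randomSimulationTest(sites, checked, probes, cutoffBp = 6000,
                     nSims = 10000, seed = 12)
```
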