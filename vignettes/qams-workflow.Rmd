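---
title: "Single-marker quantification and fingerprint evaluation: methods"
author: "qamsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification and fingerprint evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamsr)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the parameters that matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical and design choices made where the methodology
was genuinely open.

## The quantification model

Detector response is assumed linear in concentration over each analyte's
calibrated range: `A = a·c + b`, fitted by unweighted ordinary least
squares (`fit_calibration()`). Unweighted is the standard choice when a
single slope/intercept pair per analyte is the deliverable; weighted
schemes matter mostly when the calibrated range spans several orders of
magnitude, which is not the case here.

**External standard method (ESM).** Each analyte is quantified through its
own curve, `c = (A − b)/a`. Concentrations below zero (area under the
intercept) are clipped to 0 and flagged; concentrations outside the linear
range are flagged but kept, because real sample extracts routinely fall
outside the standards' validated range and rejecting them would silently
empty the table.

**Single-marker method (QAMS).** The relative correction factor of analyte
*k* against marker *s* is the slope ratio `f_k/s = a_k/a_s`
(`compute_rcf()`), and sample content is `C_k = A_k/(a_s·f_k/s)`. Two
readings of the published content equation are possible — the marker symbol
as its calibration slope, or as its sample peak area combined with a
slope-only marker concentration — and both collapse algebraically to
`C_k = A_k/a_k`, an intercept-free inversion of analyte *k*'s own curve.
This identity is what the package implements, and it fixes the exact
relationship between the two routes:

> QAMS − ESM = (b_k/a_k) × extraction factor, a constant per analyte.

The marker's own content is reported by the ESM route (full curve,
intercept included), matching the single marker column convention of the
reference study's content table; `marker_by = "slope"` forces the
intercept-free inversion for symmetry experiments.

**Extraction factor.** Converting solution concentration (mg/mL) to
content per gram of dry material needs extract volume × dilution / sample
mass (mL/g). The published sample-preparation chain for the reference study
is internally inconsistent (a 2.0 mg sample in 25 mL cannot produce the
printed mg/g contents), so the factor is never hard-coded: it is an
explicit argument, default 1, which keeps results on the raw mg/mL scale.
Reproduction of the absolute published contents is therefore not attempted;
all content-table statistics are computed from the published content table
itself, which the package ships as a fixture.

**LOD/LOQ.** The limits are defined operationally on a dilution series:
the lowest tested concentration reaching signal-to-noise 3:1 (LOD) and
10:1 (LOQ). S/N is an input here — computed upstream by the fingerprint
stage as apex height over baseline noise — which keeps the calibration
module purely tabular. When no tested concentration reaches a threshold
the result is an explicit not-determined marker, never an extrapolated
number.

## Validation statistics

All dispersion statistics use the sample (n−1) standard deviation. This is
not a stylistic choice: the between-batch CV row of the reference peak-area
table is reproduced within 0.1 percentage points by the sample sd
(gastrodin 49.68 → printed 49.7) and not by the population sd (48.5).

The ESM-vs-QAMS agreement report computes, per sample and analyte, the
relative error `100·|E−Q|/mean(E,Q)` and the pair RSD `100·sd/mean`; for a
two-value pair these are exactly tied, `relative error = √2 × pair RSD`,
and the package asserts this identity at machine precision. Using the pair
mean as denominator (rather than the ESM value) is what makes the √2
relation hold, and it is the convention visible in the reference study's
own agreement table. All-zero pairs are flagged and excluded from column
statistics; the marker, quantified identically in both tables, yields the
degenerate t = 0, p = 1 convention.

The paired t-test is `t = mean(d)/(sd(d)/√n)` with df = n−1, two-sided,
with the p-value evaluated through the regularized incomplete beta
function, `p = I_{df/(df+t²)}(df/2, ½)`; tests hold it to an independent
t-CDF oracle within 1e-9. One known discrepancy is documented rather than
hidden: the reference study's printed p-values (0.80–0.99), though labelled
paired, are numerically those of an *unpaired* two-sample comparison. A
genuine paired test on its printed contents is strongly significant for
several analytes, because the QAMS route sits systematically above ESM by
exactly the intercept term. The package follows the stated contract (paired)
and leaves the comparison of means to the user.

## Fingerprint stage

**Noise.** Baseline noise is the MAD (×1.4826) of the linearly detrended
baseline region; without a declared region, `mad(diff(y))/√2` over the
whole trace, which is robust to peaks.

**Peak detection.** Local maxima above `min_snr` × noise over a
rolling-median baseline; bounds at the valley minima on either side; area
by trapezoidal integration above the straight line joining the bounds.
Valley-to-valley with a linear local baseline is the standard integration
default absent any statement in the source methodology. A light moving
average assists apex finding only; integration always uses the raw trace.
Defaults: `min_snr = 3`, `min_width = 0.05` min (about half the narrowest
generated peak width).

**Reference and alignment.** The consensus reference is the pointwise
median (robust to a single aberrant batch) or mean of aligned traces.
Alignment is multipoint retention-time correction: peaks are matched
greedily by nearest apex within a ±0.5 min window (closest pairs first,
each apex used once, order-violating matches dropped), matched apices
become anchors of a piecewise-linear warp, and the warp offset tapers to
zero at the trace ends so that the correction is the identity outside the
anchor span and never reorders peaks. Greedy mutual-nearest matching is
simple and deterministic, and adequate at the resolution the methodology
assumes (neighbouring peaks separated with resolution > 1.5). With zero
matches the trace is returned unchanged with a warning flag.

**Similarity.** Whole-trace Pearson correlation (default) or cosine on a
common grid. Whether the original closed-source evaluation software
correlates full traces or matched-peak vectors is unstated; full traces are
the default here, and for a trace that is a sum of resolved peaks the two
are nearly equivalent anyway (the correlation is then carried by the peak
amplitudes). The commercial tool is reimplemented from its described
behaviour — median-based reference, multipoint correction, 0.5-min window,
correlation metric — and exact parity with it is not claimed.

## Chemometrics

Peak-area profiles are column z-scored (sample sd) so abundant and trace
components weigh equally; constant columns are a hard error rather than
being silently dropped, to surface degenerate inputs. Clustering is
agglomerative on Euclidean distances between z-scores. The linkage default
is Ward (`hclust`'s `ward.D2`): on the packaged 21-batch table it is one of
the linkages (with average and complete) that reproduce the published
grouping — the two batches from one distinctive origin pair together, as do
the two known-similar batches — and Ward is the conventional first choice
for compact morphological groups. The original study's heatmap software
does not document its distance, linkage, or whether rows and columns were
both clustered, so full three-group membership is treated as soft; only the
two documented pairings are asserted.

## Synthetic data generator

The generator exists so every stage can be exercised against known truth:

- **Peak shape**: exponentially modified Gaussian, area-parameterized
  (area = calibration slope × concentration exactly), with `tau = 0`
  degenerating to a pure Gaussian so analytic area checks stay exact. The
  EMG tail exercises asymmetric integration. Numerical stability uses the
  scaled complementary error function where the naive form would overflow.
- **Between-batch dispersion**: concentrations are drawn independently
  per analyte from a lognormal with `sdlog = √log(1+CV²)`, which keeps
  areas positive even at the ~97% CVs the reference study reports — a
  Normal model would go negative. Default means are the published mean
  areas divided by the calibration slopes; default CVs are the published
  CV row (32–97%).
- **Retention jitter**: one Normal(0, 0.1 min) shift per batch applied to
  all peaks, emulating run-to-run drift while keeping typical shifts
  within the 0.5-min matching window. Drift is a slow sinusoid (amplitude
  2 detector units) and noise is additive Gaussian (sd 0.5), both small
  against peak heights of 10²–10⁴, as in a well-behaved UV trace.
- **Determinism**: all randomness flows from one integer seed; the
  caller's RNG state is saved and restored, and equal seeds give
  bit-identical panels.

Default retention times place the seven peaks in the panel's elution order
over the first half of a 130-min run (10.6–66.4 min); tests and the
orchestrated synthetic run use a 0–75 min grid at 0.01 min, which covers
all peaks with full tails while keeping a 21-batch run to a few seconds.

**What the generator does not emulate — and what that means for the
tests.** Real chromatograms carry dozens of un-quantified matrix peaks and
shared baseline structure; the synthetic world contains exactly the seven
panel peaks. Whole-trace similarity of such a trace reduces to the
correlation of the seven peak-amplitude vectors, and even the *published*
peak-area table gives amplitude-vector correlations against the median
profile as low as −0.08 for the most divergent batches. High (>0.95)
fingerprint similarity across all batches, as reported for the real
instrument traces, is therefore not reachable in a seven-peak world under
the published dispersion — the synthetic similarity distribution (median
≈0.9, minimum ≈0.7 at the default settings) reflects composition
variability honestly, and passing synthetic tests demonstrate correctness
of the similarity/alignment machinery, not the real-data similarity level.
Likewise the generator models no gradient-dependent retention behaviour,
no UV spectra, and no chemical interconversion between the marker and its
aglycone.

## Numerical choices and degenerate inputs

- RCF of the marker is set to exactly 1, not a ratio of equal floats.
- Fixture tables are transcribed digit-for-digit as published — including
  one anomalous 0.00 content and two three-decimal entries — and guarded
  by frozen md5 checksums; downstream code tolerates the data as printed.
  Two published correction factors (parishin B 1.1156, parishin C 1.6771)
  deviate from pure slope ratios by 1.6e-4 and 5.9e-4 respectively; the
  printed parishin C value is unreachable from the printed slopes (interval
  arithmetic on their five digits bounds the ratio away from it), most
  plausibly because the original factors were averaged over calibration
  points that were never deposited. The package reports the slope ratios.
- Missing peak-table cells are `NA` sentinels, never 0; quantification
  propagates them as missing contents.
- Non-uniform chromatogram grids are resampled by linear interpolation;
  strictly non-monotone time axes are hard errors.
- Tie-breaking in clustering follows `stats::hclust` (lowest-index pair
  first), making runs deterministic.

## Known limitations

- Absolute contents in mg/g require an extraction factor the published
  methodology cannot supply; the package computes them only relative to an
  explicit factor.
- Agreement statistics computed from the published rounded (2 d.p.)
  contents are limited by print precision: for the lowest-abundance
  analyte (contents 0.13–0.39 mg/g) rounding alone caps the achievable
  ESM-vs-QAMS correlation near 0.992, below the 0.998 the original authors
  computed on unrounded data.
- No vendor chromatography formats, no multi-marker extension, no
  RCF transfer across instruments or columns, and no full-trace warping
  (COW/DTW); the multipoint piecewise-linear correction is intentionally
  the simple, deterministic variant.
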