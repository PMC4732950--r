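---
title: "Methods: breathing-pattern complexity analysis in respvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breathing-pattern complexity analysis in respvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respvar)
```

## Overview

`respvar` quantifies the complexity of spontaneous breathing from
breath-indexed series: the inter-breath interval (IBI, seconds, the
time between consecutive volume peaks) and the lung volume (LV,
liters, the peak amplitude of each breath). The analysis assumes a
stationary 60-minute resting recording; all indices are computed on
z-normalized series (mean 0, sample SD exactly 1, n − 1 denominator),
so subjects with different absolute rates and tidal volumes are
comparable and the entropy tolerance reads as a fraction of SD. This
vignette records the models, the parameter choices, and the places
where the design was genuinely open.

## From waveform to series

Two-band plethysmography gives rib-cage and abdomen movement signals.
Volume calibration here is a least-squares affine map from the two
bands to a reference volume signal; it reports its R² and refuses
rank-deficient (constant-band) inputs. This linear model is a
deliberate simplification — band-to-volume transfer in real equipment
is mildly nonlinear and is usually calibrated with a trained
regression model against spirometry — but it is transparent,
invertible, and exact for the simulator's linear 60/40 band mixing.

Peaks are detected as local maxima with a minimum separation of 1 s
(below any physiologic inter-breath interval) and a minimum prominence
of 0.5 signal SD (robust to asymmetric breath lobes). The IBI series
is the successive peak-time differences (length n − 1); the LV series
is the peak amplitude itself (length n). When the two are paired for
cross-sample entropy, LV drops its first element so interval k aligns
with the volume of the breath it leads into — a bookkeeping convention
the analysis is insensitive to, recorded here because some definitions
use inspiratory amplitude above the preceding trough instead of the
absolute peak value (we use the absolute peak).

Artifact handling is rule-based and logged: intervals outside
[0.5, 15] s are removed first (sneezes, coughs, movement, missed
peaks), then values more than 5 robust SDs (MAD) from the median. The
bounds rule runs first deliberately: a single spike in an otherwise
constant series must be caught even when the MAD is zero. Removing
more than 20% of a series raises a warning flag. Visual verification,
the practice in clinical recordings, has no algorithmic equivalent;
both thresholds are configurable.

## The four indices

**Detrended fluctuation analysis.** The mean-subtracted series is
integrated; for each box size n the profile is split into ⌊N/n⌋
non-overlapping boxes, a least-squares line is removed per box
(DFA-1), and the RMS residual F(n) is recorded. α is the slope of
log F(n) against log n. Box sizes default to ~15 log-spaced integers
from 4 to N/4 — the standard range over which the fit is linear for
fractal signals (the regression R² is reported; on synthetic 1/f
series of 1024 points it exceeds 0.98). Anchors: α = 0.5 white noise,
1.0 for 1/f, 1.5 for Brownian noise; the estimator reproduces
(β + 1)/2 within ±0.1 across β ∈ [0, 2] (mean over 10 seeds).

**Sample entropy.** SampEn(m, r) = −ln A/B with B the number of
template pairs (Chebyshev distance, tolerance r·SD, templates i ≠ j,
both indices ranging over the N − m templates that have a
continuation) matching at length m, and A those still matching at
m + 1. Defaults m = 2, r = 0.2, the convention for breath and
heart-rate series. For iid Gaussian data the statistic has the closed
form −ln(2Φ(r/√2) − 1) ≈ 2.19 at r = 0.2, which the implementation
reproduces within 5% at N = 10⁴ and matches an O(N²) brute-force
counter exactly at small N. A = 0 (no continuation matches, common on
short regular series) returns a flagged `Inf` rather than an error so
cohort runs survive.

**Cross-sample entropy.** The same statistic with templates from the
IBI series matched in the LV series (ordered pairs; there is no
self-match concept across distinct series), tolerance r times the
pooled SD (= r for z-normalized inputs). The statistic is
direction-dependent and the direction is recorded; a symmetrized mean
is available by flag. One behavior worth knowing: for jointly
Gaussian series, linear coupling scales the m- and (m+1)-match counts
together, so the *conditional* ratio barely moves until the residual
between the two series falls inside the tolerance — cross-sample
entropy is a detector of strong synchronization (residual ≲ r·SD),
not a linear-correlation meter. The simulator's group coupling values
are chosen with this threshold in mind (see below).

**Largest Lyapunov exponent.** Rosenstein's small-data-set method:
delay-embed the series, pair each point with its nearest neighbor at
temporal separation beyond a Theiler window (default: the dominant
period from the periodogram peak, so same-cycle neighbors are never
paired), then average log pair-distance over i = 1, 2, … steps; the
exponent is the least-squares slope over steps 1–10 (configurable).
One step = one breath. On logistic-map series (r = 4) the chain
recovers the analytic exponent ln 2 within a few percent; on a pure
sinusoid the divergence curve is flat (estimate ≤ 0.05).

### Embedding selection

The delay comes from the average mutual information curve I(lag)
(histogram estimator, 16 bins): the first interior local minimum that
is followed by a genuine rise (at least 10% of the drop from I(1)),
else the first lag where I falls below I(0)/e, else lag 1. A guard
runs first: a series already linearly decorrelated at lag 1
(|acf(1)| < 1/e) takes tau = 1 directly. The guard matters: for
white-spectrum deterministic maps the AMI beyond lag 1 is estimator
noise plus the signature of the *iterated* map, and a delay selected
there makes the iterated map's steep derivative trip the
false-neighbor ratio test downstream. A caveat discovered while
validating: a noiseless sinusoid sampled commensurately (integer
period) takes only `period` distinct values, so its AMI curve has a
flat valley starting at lag 2 rather than a sharp quarter-period
minimum; with phase-spreading noise the classic quarter-period
minimum reappears (period 20 → tau = 5).

The dimension comes from false nearest neighbors (delay as above):
a neighbor is false if adding the next coordinate inflates its
distance by more than rtol = 15, or pushes it beyond atol = 2 series
SDs; the selected dimension is the smallest with < 1% false
neighbors, capped at 10 (6 inside the Lyapunov chain) with a
saturation flag — stochastic signals saturate by construction, which
is expected for breathing data and simply means the embedding is a
working approximation rather than a reconstruction. Neighbors
coincident to machine precision (exact recurrences of periodic
orbits) are excluded from the ratio test by a distance floor of
1e−8 SD; without it, floating-point jitter of order 1e−16 produces
spurious false-neighbor flags on perfectly periodic signals. For
short series the candidate dimension is additionally capped so at
least 100 embedded vectors remain.

## The synthetic cohort

No recordings ship with the package; the simulator stands in for
them, with known ground truth.

Per-breath sequences are driven by colored noise generated in the
frequency domain (amplitudes ∝ f^(−β/2), random phases, standardized),
giving exact spectral control and the DFA expectation α = (β + 1)/2.
Intervals and amplitudes come from a lognormal link
m·exp(s·u − s²/2) with s = √log(1 + CV²) and the driver u clipped at
±4 SD — this imposes the requested mean and CV while keeping
intervals positive even at the largest group CV (0.51). The IBI and
LV drivers share a common component with correlation `coupling`. The
waveform renderer draws each breath as a half-sine lobe centred on
its peak and splits it 60/40 across the rib-cage/abdomen channels,
plus a small band-specific wiggle that cancels in the weighted sum —
so calibration recovers (0.6, 0.4) exactly and the drawn peak table
is the renderer's exact ground truth.

Group defaults: the mean and CV of IBI and LV per group are the
published descriptive statistics for healthy adults and the three
asthma phenotypes (e.g. healthy IBI 3.51 s at CV 0.13, LV 0.64 L at
CV 0.27). The spectral exponents (1.0 / 0.7 / 0.45 / 0.25 for IBI)
and couplings (0.3 / 0.8 / 0.97 / 0.99) are *synthetic* choices —
no numeric group means for the complexity indices are published — set
once so the simulated cohort exhibits the qualitative clinical
ordering: long-range correlation falls from health toward
uncontrolled asthma, and IBI–LV synchronization strengthens enough in
uncontrolled disease to cross the cross-entropy tolerance threshold
discussed above.

What the simulator does *not* emulate: real breathing is
non-Gaussian, and in patients both the DFA exponent and sample
entropy fall together. A single Gaussian driver cannot do that — a
whiter driver (lower α) is necessarily *more* irregular (higher
SampEn) — so in the synthetic cohort the SampEn group ordering runs
opposite to the clinical one while DFA, cross-SampEn and the
classifier behave as intended. Passing tests therefore demonstrate
correctness of the estimators and the pipeline on signals with known
structure, not fidelity of every index's clinical direction. Sneeze
and cough artifacts and sensor physics are likewise out of scope.

## Classification and evaluation

The weighted ℓ₀ objective is NP-hard; the implementation is greedy
weighted matching pursuit — select the column maximizing
|correlation with residual|/wₖ, refit by least squares on the support,
stop at the budget (default min(10, ⌈n/4⌉)) or at negligible
residual. Weights are Minkowski distances (default order p = 2, the
order being otherwise unspecified in the WSRC literature we follow)
rescaled to [1e−6, 1]; nearer training samples are penalized less.
Ties between class residuals resolve to the class with more absolute
coefficient mass, then to label order, making runs deterministic.
LOOCV standardizes features with training-fold statistics only; the
suite verifies predictions are invariant to feature rescaling.

ROC curves sweep all observed thresholds; AUC is the trapezoid area
(equal to the Mann–Whitney concordance with ties counted half — the
suite checks this against exhaustive pair counting for every n ≤ 30
instance), SE follows Hanley–McNeil, and the reported p tests
AUC = 0.5 by normal approximation. Curve orientation is chosen so
AUC ≥ 0.5 and recorded. Cut-offs maximize the Youden index, ties
resolved toward higher specificity. Proportion CIs are exact binomial
(Clopper–Pearson) — chosen because the printed small-sample bounds
for 100% sensitivity/specificity (88–100 at n = 30, 69–100 at
n = 10, 83–100 at n = 20) are exactly the exact-binomial ones —
and likelihood-ratio CIs use the log method, with `Inf`/`NaN`
conventions for empty cells. Group comparisons use one-way ANOVA with
Bonferroni pairwise t-tests when every group passes Shapiro–Wilk,
otherwise Kruskal–Wallis with a hand-rolled Dunn post-test
(tie-corrected rank z-statistics, Bonferroni-adjusted).

## Problem sizes and reproducibility

Defaults follow the recording protocol: 60-min series (≈ 1000
breaths), 1 kHz waveform sampling. The test suite trades duration for
speed where the property under test allows it (10–40 min simulated
recordings, 2^12–2^14-point calibration series, N ≤ 500 for exact
entropy oracles); the calibration script uses 2^14-point series, 10
seeds per noise class, and 5 logistic-map runs of 5000 points. Every
generator is a pure function of its arguments including the seed, and
`run_pipeline` stamps each artifact with the configuration hash, so
reruns are bit-identical.

## Known limitations

* The linear volume calibration underfits genuinely nonlinear
  band-to-volume transfer; it fills the pipeline slot, not the
  metrological one.
* Cross-sample entropy's threshold behavior means moderate linear
  coupling (residual above r·SD) is invisible to it.
* FNN saturates on stochastic signals; the reported dimension is then
  the cap, flagged, and the Lyapunov estimate for such signals should
  be read as a divergence-rate statistic, not evidence of chaos.
* The synthetic cohort reverses the clinical SampEn ordering (see
  above) and its index distributions are not claimed to match any
  patient population.
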