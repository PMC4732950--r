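# respvar

Nonlinear complexity analysis of breathing pattern variability.

Spontaneous human breathing is not metronomic: both the inter-breath
interval (IBI) and the breath-by-breath lung volume (LV) fluctuate in a
structured, fractal-like way, and that structure degrades in airway
disease. `respvar` implements the full analysis chain used to exploit
this clinically — from two-band respiratory inductive plethysmography
waveforms to per-subject complexity indices, a sparse-representation
diagnostic classifier, and ROC-based evaluation — together with a
synthetic cohort simulator that makes every stage testable without any
patient data.

## What it computes

For each subject's z-normalized IBI and LV series the package derives
seven indices:

* **DFA scaling exponent** α — slope of log F(n) vs log n after
  integrating the series and removing local linear trends in boxes of
  size n. α = 0.5 for uncorrelated noise, α = 1 for 1/f fractal
  dynamics, α = 1.5 for Brownian noise. Computed for IBI and LV.
* **Sample entropy** SampEn(m, r) = −ln A/B, the conditional
  probability that templates matching for m points (Chebyshev distance,
  tolerance r·SD, self-matches excluded) still match at m + 1. Lower =
  more regular. Defaults m = 2, r = 0.2. Computed for IBI and LV.
* **Cross-sample entropy** between IBI and LV — the same statistic with
  templates drawn from one series and matched in the other; lower
  values mean stronger IBI–LV synchronization.
* **Largest Lyapunov exponent** by the Rosenstein small-data-set
  algorithm — the slope of the mean log-divergence curve
  d(i) = d(0)·e^(LLE·i) of nearest-neighbor trajectory pairs in a
  delay embedding, with delay chosen by average mutual information and
  dimension by false nearest neighbors. Computed for IBI and LV.

Subjects (labelled Healthy / CAA / UAA / UNAA — controlled atopic,
uncontrolled atopic, uncontrolled non-atopic asthma) are then
classified with a **weighted sparse representation classifier**
(WSRC): a test profile y is represented as a sparse combination of
training profiles A, solving the weighted sparsity objective
x̂ = argmin Σₖ wₖ|xₖ|₀ s.t. y ≈ Ax by greedy weighted matching pursuit,
where wₖ is the Minkowski distance from y to training sample k; the
predicted class minimizes the class-restricted reconstruction residual
‖y − A δ_c(x̂)‖₂. Performance is evaluated by leave-one-out
cross-validation, sequential forward feature selection, ROC curves
(trapezoid AUC, Hanley–McNeil SE, Youden cut-offs) and diagnostic
metrics with exact binomial confidence intervals.

## Worked example

```r
library(respvar)

## simulate a 10-min two-band plethysmography recording and extract breaths
w <- breath_waveform(breath_spec(duration = 600, seed = 42), fs = 50)
breaths <- detect_breaths(w$waveform$volume_ref, fs = 50)
s <- series_from_breaths(breaths)
summary_stats(s$ibi)[c("mean", "cv")]
#> $mean [1] 3.488941      $cv [1] 0.1296014

complexity_profile(s$ibi, s$lv)
#> Complexity profile:
#>            DFA_IBI             DFA_LV         SampEn_IBI          SampEn_LV
#>             0.8589             0.8690             1.7309             2.0557
#>            LLE_IBI             LLE_LV CrossSampEn_IBI_LV
#>             0.1027             0.0753             1.8543

## a full 4 x 10 synthetic cohort (60-min series per subject)
cohort <- simulate_cohort(seed = 1)
round(tapply(cohort$features[, "DFA_IBI"], cohort$labels, mean), 2)
#> Healthy     CAA     UAA    UNAA
#>    0.99    0.85    0.74    0.62

loocv_wsrc(cohort, task = "asthma_vs_healthy", features = "preset:ibi_all")
#> LOOCV-WSRC accuracy: 97.5%
#>          predicted
#> truth     Asthma Healthy
#>   Asthma      30       0
#>   Healthy      1       9

roc_analysis(cohort$features[, "DFA_IBI"],
             task_labels(cohort$labels, "asthma_vs_healthy"))
#> AUC = 1.00 (95% CI 1.00-1.00), SE = 0.00, p = 0
#> cut-off 0.9: Se 100.0% (88-100), Sp 100.0% (69-100)
```

The group means show the intended gradient: long-range correlation of
the breathing rhythm (DFA α) declines from near 1 (healthy 1/f
dynamics) toward 0.5 (uncorrelated) as asthma worsens, and a single
index already separates asthma from health (AUC 1.00 on this cohort;
sensitivity and specificity carry exact binomial CIs, hence 88–100 at
n = 30 and 69–100 at n = 10 even for perfect classification).

`run_pipeline(default_config(seed = 1))` runs the whole chain —
simulate → profile → classify → evaluate — and can write a
reproducible artifact bundle (tidy cohort CSV, classification and ROC
JSON, each stamped with the configuration hash and seed).

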