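# dualtrack

Time-resolved EEG decoding of the simultaneous attentional selection of two
targets, with a trial-wise classifier-confidence correlation diagnostic for
serial versus parallel selection — and the simulation framework that
validates it.

## The problem

When observers look for two targets at once — one on the horizontal
meridian (left/right), one on the vertical meridian (top/bottom) — does
attention select them serially, in parallel under a common mechanism, or in
parallel and independently? `dualtrack` addresses this with multivariate
decoding of epoched EEG:

* **Per-timepoint decoding.** For every time sample, a linear discriminant
  (pooled covariance with Ledoit–Wolf shrinkage, equal priors) is trained
  on the 64-channel voltage vector to classify the horizontal target
  position, and a second one the vertical position, under 10-fold
  cross-validation with within-class undersampling and between-class
  interpolation oversampling. Performance is the rank-based AUC; classifier
  weights are forward-transformed (Σw) into interpretable activation maps.
* **Group inference.** Sample-wise t-tests with cluster-based sign-flip
  permutation correction (cluster mass = summed t over contiguous
  suprathreshold samples), and jackknife fractional-peak onset latencies:
  leave-one-out group averages, 3-point smoothing, onset at 50% of the
  peak's elevation above chance, contrasted with the corrected statistic
  t_c = t_naive / (n − 1).
* **The dependency diagnostic.** Per trial and timepoint, each classifier's
  confidence (signed distance from the decision boundary, oriented toward
  the trial's true class) is extracted; Spearman's ρ across trials between
  the two classifiers indexes inter-target dependency. Serial selection
  predicts ρ < 0, a common parallel mechanism ρ > 0, independent parallel
  selection ρ ≈ 0.
* **Validation by simulation.** A synthetic-EEG generator injects a
  half-sine 1 µV ERP (200–600 ms) with +/− polarity on an orthogonal
  8-channel contra/ipsilateral split, with a known inter-target correlation
  (positive, negative, or null) and parametric SNR (peak amplitude over
  maximum uniform-noise amplitude, 17 levels from 4 to 0.04).
  `snr_sensitivity_sweep()` maps out at which decoding strength an injected
  correlation is reliably recovered.
* Also included: rule-based preprocessing (baseline correction, RT/accuracy
  screening, horizontal-EOG step detection, 110–140 Hz EMG band-power
  rejection) and the conventional N2pc contra-minus-ipsi analysis at
  PO7/PO8.

See the methods vignette (`vignettes/dualtrack-methods.Rmd`) for the full
model description and design rationale.

## Worked example

Simulate a 6-subject cohort with a *negative* injected correlation (serial
selection: on every trial exactly one of the two targets carries the ERP)
at SNR 4, and run the full pipeline:

```r
library(dualtrack)
cfg <- run_config("ci", n_subjects = 6, n_trials = 128, seed = 42L)
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result> 6 subjects, 77 timepoints
#>   group peak AUC 0.847 at 567 ms; mean onset 216 ms
#>   mean trial-wise rho in ERP window: -0.273
print(res$rho_cluster)
#> <cluster_result> 4 cluster(s), alpha = 0.05, 500 permutations
#>  start end start_ms   end_ms        mass   p_value significant
#>      4   4 129.6875 129.6875    2.760449 0.7564870       FALSE
#>     10  10 176.5625 176.5625   -4.488118 0.2255489       FALSE
#>     15  63 215.6250 590.6250 -830.071811 0.0259481        TRUE
#>     77  77 700.0000 700.0000   -4.308141 0.2614770       FALSE
```

Both dimensions decode well above chance (group peak AUC 0.847) — mean
decodability cannot tell serial from parallel, because each target's ERP is
present on half the trials either way. The trial-wise confidence
correlation is what carries the signature: a significant *negative* cluster
spanning 216–591 ms (mass −830, p = 0.026), exactly the injected serial
structure. Per-subject peak-AUC summaries tell the same story:

```r
head(res$peak_summary[, c("subject", "dimension", "peak_auc", "rho_at_peak")], 4)
#>   subject  dimension  peak_auc rho_at_peak
#> 1       1 horizontal 0.9213333  -0.3137755
#> 2       1   vertical 0.9193333  -0.2546813
#> 3       2 horizontal 0.9333333  -0.3081824
#> 4       2   vertical 0.9400000  -0.4155650
```

Rerunning with `correlation_mode = "positive"` flips the cluster's sign;
`"null"` leaves ρ flat at zero while AUC is unchanged — the three outcomes
the diagnostic is built to distinguish.

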