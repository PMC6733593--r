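---
title: "Tracking two attentional targets at once: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking two attentional targets at once: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When observers search for two differently defined targets at the same time,
selection of one could proceed serially (at the expense of the other),
in parallel under a shared resource, or in parallel and independently.
`dualtrack` implements an EEG decoding approach to this question. Two
targets are placed on orthogonal spatial axes — one on the horizontal
meridian (left/right), one on the vertical meridian (top/bottom) — so that
two linear classifiers, trained on the multichannel EEG at every time
sample, track the attentional selection of each target separately. The
decisive evidence does not come from mean decoding accuracy but from the
*trial-wise co-variation of classifier confidence*: if selection is serial,
a trial with high confidence about one target should show low confidence
about the other (negative correlation); a common parallel mechanism
predicts positive correlation; independent parallel selection predicts
none.

Because "no correlation" is a null result, the package also implements the
validation that makes the diagnostic interpretable: a synthetic-EEG
generator with a *known* injected correlation structure and a parametric
signal-to-noise ratio (SNR), used to establish at which decoding strength
an existing correlation would have been detected.

## The synthetic-EEG generator

`generate_dataset()` simulates one subject's epoched EEG under the same
conditions as the recorded experiment it emulates:

* 512 trials of 64 channels at 512 Hz, epochs from −300 to 800 ms;
* the attention ERP is half a cycle of a sine wave, 1 µV peak, spanning
  200–600 ms (`make_erp_kernel()`); its closed form at time $t$ is
  $A\sin\!\big(\pi (t-t_{on})/(t_{off}-t_{on})\big)$ inside the window and
  exactly zero outside;
* eight posterior channels carry signal. The horizontal target writes the
  kernel with + sign on one half of them and − sign on the other
  (contralateral/ipsilateral relative to the trial's class); the vertical
  target uses an *orthogonal* split of the same eight channels, so the two
  spatial patterns are orthogonal channel-space vectors and the two
  dimensions carry independent information by construction. The default
  split places PO7/PO8 among the horizontal pair so the conventional N2pc
  electrodes resolve on simulated data;
* the inter-target dependency is injected through the per-trial ERP
  presence flags (`draw_presence()`): *positive* — the ERP is present for
  both targets on exactly half the trials and absent for both on the other
  half; *negative* — present for exactly one target per trial, never both;
  *null* — presence drawn independently per dimension with probability ½.

**SNR convention.** SNR is the ratio of the kernel's peak amplitude to the
*maximum* noise amplitude. A hard maximum is only well defined for bounded
noise, so noise is i.i.d. uniform on
$[-A/\mathrm{SNR},\,+A/\mathrm{SNR}]$ per trial, channel and sample; the
bound is therefore bit-exact and attained. A Gaussian option
(σ = bound/3) is available behind `noise = "gaussian"` for users who
prefer unbounded noise; the uniform default is what every test and the
sensitivity sweep use. Noise is added to all 64 channels, the 56
non-signal channels being pure noise, so the decoder faces the same
feature space as the real analysis.

Class labels on ERP-absent trials are assigned balanced at random: those
trials carry chance-level information only, which is deliberate — it is
exactly what makes the negative mode's *mean* decodability stay above
chance on both dimensions while the trial-wise confidence correlation goes
negative.

Behavioral metadata (correctness ~ Bernoulli(0.95), shifted-lognormal RTs
around 700 ms, blocks of 32 trials, four equiprobable target colors) are
generated so the response-based screening and the switch/repeat split run
end-to-end on simulated data; these are plumbing realism, not modeled
quantities.

All randomness flows from one master seed through `derive_seed()`, a fixed
affine hash of (seed, stage tag, index) modulo $2^{31}-1$: per-subject,
per-stage and per-fold streams are independent and each stage is
reproducible in isolation.

**What the generator does not emulate:** volume conduction from a head
model, 1/f or autocorrelated background EEG, eye/muscle artifacts with
realistic morphology, inter-subject variability of ERP topography or
latency. Passing tests therefore demonstrate the correctness and
sensitivity of the *analysis machinery* under the stated generative model,
not the physiological realism of the signal.

## Preprocessing

`preprocess_epochs()` chains, in fixed order:

1. **Baseline correction** — per trial and channel, subtract the mean over
   −100…0 ms.
2. **Response screening** — flag incorrect trials, anticipations
   (RT < 200 ms), and slow outliers (RT > block mean + 3 SD). Block mean
   and SD are computed once per block over correct trials before any
   exclusion; the rule is single-pass, not iterated.
3. **Horizontal-EOG step detection** — a 100 ms window slides in 50 ms
   steps over 0–500 ms; a trial is flagged when the second-half mean and
   first-half mean of any window differ by ≥ 30 µV. The statistic uses
   within-window differences only, so it is invariant to constant offsets.
   The split-half window-mean ("step function") detector is the
   conventional choice where only threshold/window/step are specified.
4. **EMG rejection** — trials are band-pass filtered at 110–140 Hz
   (4th-order Butterworth, zero-phase `filtfilt`), summarized by total
   band power, z-scored across trials, and flagged above
   `max(3, 3·SD(z))`. Since z-scores have unit SD by construction the
   default reduces to a fixed cutoff of 3; the rule is exposed
   (`z_min`, `z_mult`) and the realized cutoff is attached to the mask.

Each rejected trial carries exactly one reason code — the first rule that
fired (`rt_fast`, `rt_slow`, `incorrect`, `eog_step`, `emg`; `visual` is
reserved for a manual stage that the package does not automate). An
ICA-based blink-removal stage is represented by the pass-through hook
`remove_blink_components()`, which accepts a user-supplied cleaning
function for real recordings. No offline filters are applied to the data
used for analysis.

## Per-timepoint decoding

`crossval_decode()` trains, for each time sample and cross-validation
fold, a binary linear discriminant on the 64-channel voltage vector:

* **Folds.** Trials are shuffled and dealt into ten folds; assignment is
  stratified by class so both classes appear in every fold even at small
  trial counts. Each fold serves as test set once; performance is averaged
  over folds.
* **Within-class balancing.** Before fold assignment, trials are
  undersampled so that within each class of the decoded dimension the two
  levels of the orthogonal dimension are equally frequent — otherwise the
  left/right classifier could exploit top/bottom information.
* **Between-class balancing.** Training folds (never test folds) are
  topped up by interpolation-based oversampling: each synthetic trial is a
  convex combination of a minority-class trial and one of its k = 5
  nearest minority neighbors (whole epochs are interpolated; neighbor
  distances are computed on the flattened trial tensors). A single-sample
  minority class falls back to duplication with a warning.
* **The classifier.** Pooled-covariance LDA with equal priors. With 64
  channels and a few hundred trials the pooled covariance is
  ill-conditioned, so it is shrunk toward a scaled identity with the
  Ledoit–Wolf closed-form intensity estimated per timepoint and fold
  (`shrinkage = "none"` restores plain LDA). Decision scores are the raw
  signed distances $w^\top x + b$; positive scores predict the
  first-listed class ("left"/"top").
* **AUC.** Rank-based (Mann–Whitney) area under the ROC curve, ties
  counted one half; verified in the tests against an exhaustive
  $O(n^2)$ pairwise oracle.
* **Confidence.** Every retained trial receives its signed distance from
  the fold in which it was test data — no probability calibration, per the
  distance-from-boundary definition.
* **Activation maps.** Classifier weights are not interpretable as
  sources; the forward-model pattern $\Sigma w$ (training-data covariance
  times weights) is. The per-timepoint pattern is computed as
  $X_c^\top (X_c w)/(n-1)$, avoiding the explicit covariance; the tests
  confirm it recovers the injected ± channel template at high SNR.

Each timepoint is decoded from that sample's channel vector only; no
temporal windowing, no train-time × test-time generalization.

## Group statistics

**Cluster-based permutation test.** Pointwise two-sided one-sample t
(against 0.5 for AUC, 0 for differences and correlations; paired mode
tests the difference of two matched matrices). Samples exceeding the
pointwise threshold (α = 0.05 on the t distribution) form contiguous
clusters of consistent sign, scored by summed t ("mass"). The null
distribution of the maximum |mass| is built from random per-subject sign
flips (5000 by default); the observed statistic is included in the null
set so p ≥ 1/(n_perm + 1). Only temporal adjacency is used — no channel
neighborhoods. Note the hard floor this implies for small cohorts: with
$n$ subjects a two-sided sign-flip p cannot fall below $2/2^{n}$, so
detection at α = 0.05 needs at least six subjects.

**Jackknife fractional-peak onsets.** Leave-one-out group averages are
smoothed with a 3-point moving average; the peak is located in the search
window (150–700 ms by default); onset is the first sample at or above
50% of the peak's *elevation above chance*. Referencing the criterion to
chance (0.5 for AUC, 0 for difference waves) rather than the raw score is
a deliberate choice: raw AUC never falls much below 0.5, so a raw-value
50% criterion would be degenerate. The fraction and the chance reference
are both arguments. Ties at the crossing resolve to the first at-or-above
sample. The corrected contrast divides the naive paired t on the
leave-one-out onsets by n − 1; the identity
$t_c (n-1) = t_{\text{naive}}$ is asserted in the tests.

**Switch/repeat split.** Trials are partitioned by whether the target
color repeats the previous trial's within the same block; block-initial
trials are excluded.

## The dependency diagnostic

`trialwise_confidence_correlation()` computes Spearman's ρ across trials
between the two classifiers' confidence, separately per timepoint. Before
correlating, confidence is by default *correctness-referenced*: each
trial's signed distance is oriented toward that trial's true class, so
"high confidence about the target" means the same thing on left and right
trials. The raw-signed alternative is available (`orient = FALSE`); with
raw signs, a left/right classifier's distances change sign between the
two halves of the trials and the across-trial correlation with the other
dimension is diluted toward zero even when a dependency exists. The
group-level test on the per-subject ρ time courses is the same sign-flip
cluster permutation test, applied directly to the ρ values.

Per-subject summaries complement the group test: `timecourse_correlation`
(Spearman ρ between the two AUC time courses in 150–700 ms) and
`peak_auc_correlation` (the trial-wise ρ read out at each subject's
peak-AUC timepoint, per dimension).

`snr_sensitivity_sweep()` closes the loop: for each injected mode and each
SNR on the 17-level grid (4 down to 0.04), it simulates a cohort, runs the
full decode-and-correlate pipeline, and records the peak group AUC, the
mean ρ in the ERP window, and whether the group cluster test detected a
correlation with the injected sign. The sweep reproduces the method's
operating characteristic: injected correlations are reliably recovered
while peak AUC remains above roughly 0.55–0.60 and are lost below it.
For null mode the "detection" column is the false-positive indicator; its
rate is a property of the cluster test's calibration, which the test
suite measures directly over replicates rather than from single cells.

## The N2pc path

`lateralized_difference()` computes the conventional contralateral-minus-
ipsilateral difference wave at PO7/PO8 (contra = PO8 for left targets,
PO7 for right targets), averaged over trials with a lateral target and
collapsed over the vertical target position. In the noise-free limit of
the simulation this wave equals exactly twice the injected kernel — the
+A contralateral and −A ipsilateral contributions add. `n2pc_metrics()`
quantifies peak amplitude and jackknife 50%-peak onset in the 200–350 ms
window using the same machinery as the decoding latencies (chance
reference 0, negative polarity by default) plus the cluster permutation
test against zero.

## Numerical and design choices

* **Noise family** — uniform by default (the only family for which a
  maximum-amplitude SNR is exact); Gaussian behind a flag.
* **Covariance regularization** — Ledoit–Wolf shrinkage to scaled
  identity, closed form, per timepoint/fold; never raises on singular
  covariance.
* **Stratified fold dealing** — preserves the equal-size invariant
  (sizes differ by ≤ 1) while guaranteeing both classes in every fold.
* **Permutation p floor** — observed statistic counted in the null set.
* **Degenerate inputs** — flat (never-above-chance) series yield NA
  onsets with a warning rather than an arbitrary latency; zero-variance
  EMG power yields no rejections; single-sample minority classes
  duplicate rather than interpolate.
* **Serialization** — epochs round-trip bit-exactly through RDS with a
  plain-text CSV sidecar for the trial table; masks, sweep tables and
  reports are CSV/JSON.

## Problem sizes

The generator's defaults are the full study conditions (512 trials, 64
channels, 512 Hz, 24-subject cohorts, 17 SNR levels, 5000 permutations).
The test suite exercises the same code paths at a reduced "CI profile" —
typically 8 subjects, 64–128 trials, 8–64 channels at 128 Hz, 3 SNR
levels, 200–500 permutations — chosen as the smallest sizes at which each
scientific property under test is comfortably identifiable (for example,
eight subjects clear the $2/2^n$ sign-flip floor with room to spare). The
acceptance script runs the full 512-trial, 64-channel, 512 Hz simulation
with 8-subject cohorts.

## Limitations

* White uniform noise makes per-timepoint samples independent; real EEG's
  autocorrelation would widen cluster null distributions. The cluster
  test is calibrated here under the generative model, as verified by the
  family-wise-error test, not under real-EEG dependence.
* The confidence-correlation diagnostic detects dependencies that are
  consistent in sign across the ERP window; short or alternating
  couplings could cancel.
* The ICA blink stage is a hook, not an implementation; real-data use
  requires supplying a cleaning function or pre-cleaned epochs.
* Reading native acquisition formats (e.g. BioSemi BDF) is out of scope;
  real data enter through `epochs_set()` constructed from any epochs
  source.
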