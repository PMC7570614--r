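---
title: "Methods: forehead fNIRS sensor-location analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forehead fNIRS sensor-location analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fnirsloc` asks a device-design question with a statistical answer: if a
forehead-worn fNIRS system is reduced to one sensing location, how much
cognitive-workload classification accuracy is lost relative to sensing the
whole forehead? This vignette documents the models, conventions and design
choices behind each stage, and what the synthetic data can and cannot
establish.

## Session model and simulator

A session is a fixed block design: 10 s baseline, 48 s of a positional
2-back task (24 events of 2 s), 25 s rest, sampled at 25 Hz on 12 channels,
2075 samples in all (`fnirs_design()`).

The simulator works in concentration space and maps to detector intensities
through the same optical model the analysis inverts:

1. **Activation.** A task boxcar is convolved with a double-gamma impulse
   response (peak 6 s, undershoot 16 s at ratio 1/6 — the common block-design
   convention) and scaled per channel. Deoxyhemoglobin is an anticorrelated,
   lagged copy (ratio −1/3, lag 1 s), typical of observed HbR dynamics. The
   default spatial profile is mid-weighted: 1.0 µM peak ΔHbO2 on channels
   5–8, 0.6 µM on 3–4/9–10, 0.3 µM on 1–2/11–12, emulating
   frontopolar-dominated working-memory activation so that the qualitative
   location ordering is recoverable from synthetic data. No generative model
   is prescribed by the original study (it used human subjects); these are
   this package's choices, fixed once.
2. **Noise.** Sinusoids at the Mayer-wave (0.1 Hz, 0.3 µM), respiratory
   (0.25 Hz, 0.2 µM) and cardiac (1.1 Hz, 0.2 µM) bands with random phases
   per channel, a linear drift up to ±0.2 µM/min, and white noise
   (SD 0.05 µM). Amplitudes are µM-equivalents added in concentration space.
   The Mayer component deliberately sits inside the analysis pass band —
   in-band physiological confounds are the realistic hard case.
3. **Optics.** The modified Beer–Lambert law in the forward direction,
   `I(t,λ) = i0·10^(−(ε_HbO2 ΔHbO2 + ε_HbR ΔHbR)·d·DPF(λ))`, with d = 3 cm
   and DPF 6.2/5.1 at 770/850 nm, plus optional multiplicative shot noise.
   Extinction coefficients are not hard-coded: they load from
   `extdata/extinction_coefficients.csv` (Prahl/Cope compilation values in
   cm⁻¹ mM⁻¹, converted to the package's µM convention). The printed DPF
   unit "cm" is treated as the dimensionless pathlength factor multiplying
   d — the standard MBLL form. Concentration unit is µM throughout; the
   constants table's units are chosen to match, and because the simulator
   and the analysis share one table, round-trip identities hold regardless
   of which compilation is used.
4. **Behaviour.** Per-session 2-back accuracy is Gaussian (mean 96 %,
   SD 4 %) clipped to [0, 100], so the 90 % screening rule fires
   occasionally; motion is a boolean flag with probability 0.05. Motion
   waveforms themselves are out of scope — screening only needs the flag.

Every stochastic stage derives a 32-bit sub-seed from the master seed and a
stage tag, so a dataset is a pure function of `(config, seed)`.

What the simulator does **not** emulate: layered scalp/skull optics and
channel sensitivity profiles, motion artifact waveforms, serial
autocorrelation of real physiological noise, inter-subject variability in
HRF shape, or extracerebral contamination. Passing tests on synthetic data
therefore demonstrate that the pipeline's inferential machinery behaves
correctly under its assumed signal model — not that real-world accuracies
would match.

## Preprocessing

Order is fixed: screening → band-pass → moving average → optical density →
Beer–Lambert. Filters act on raw intensities before conversion, following
the described acquisition chain; the description "low-pass filtered with a
third-order Butterworth bandpass" is contradictory on its face and is
implemented as a band-pass with the stated 0.01–0.5 Hz corner pair, order 3.

Numerical choices:

* **Zero-phase filtering.** The Butterworth filter is applied
  forward–backward (`signal::filtfilt`) by default so windowed features are
  not lag-shifted; the effective order doubles. A causal single pass is
  switchable (`filter_spec(zero_phase = FALSE)`).
* **Mean restoration.** A band-pass rejects DC; filtering is applied to the
  demeaned intensity and the channel mean is restored, keeping intensities
  positive for the log-ratio step without altering the pass band.
* **Moving average.** 2 s centred window; at the edges the window shrinks to
  the available samples rather than truncating, preserving the full 10 s
  baseline. Whether the original average was causal or centred is unstated;
  centred is the phase-neutral choice consistent with zero-phase filtering.
* **Optical density.** `I₀` is the per-channel mean over the baseline
  markers; `ΔOD = −log10(I/I₀)`. Non-positive intensities are a hard error.
* **MBLL.** The 2×2 system is solved exactly per sample/channel; a singular
  extinction matrix is an error. With noise and filters off,
  `mbll(to_optical_density(forward_optics(x)))` recovers concentrations to
  below 1e−6 relative error (tested at numerical precision).

## Segmentation

Window lengths 5, 10, 20, 25 and 48 s with roughly 50 % overlap. The
printed per-session counts, not the overlap fraction, drive every
downstream sample size, so the counts are pinned as policy defaults —
(18, 11), (9, 5), (4, 2), (2, 1), (1, 1) task/rest windows — and starts are
spaced evenly across each period, which lands the overlap near 50 % at
every length. Two resolved inconsistencies: a strict 50 % rule cannot
reproduce the printed (9, 5) tuple at 10 s, hence the pinned counts; and
the printed 5 s tuple (1, 11) contradicts the printed 290-sample total,
resolved as (18, 11) which restores 10 × 29 = 290. A stray mention of a
15 s window appears nowhere in the stated window list and is treated as a
typo. Fractional start times are converted to sample indices by half-up
rounding; the whole-period setting (48 s) takes the entire 25 s rest block
as its single rest window. The baseline is never segmented, and windows
never cross marker boundaries.

## Features

11 features per channel and window: mean, variance, slope, skewness and
kurtosis of ΔHbO2 and of ΔHbR, plus their Pearson correlation. Conventions,
chosen to match the generic behaviour of the original implementation
environment and switchable in code where they matter: variance uses the
n−1 divisor; skewness is the biased moment estimator; kurtosis is
non-excess (Gaussian → 3); "slope of polynomial fit" is read at its lowest
order, a degree-1 least-squares slope per second. Zero-variance segments
get skewness/kurtosis/correlation 0 with a warning rather than NaN, so
feature matrices stay complete. Locations restrict columns: 44 features for
Left/Mid/Right, 110 for Left-Mid/Right-Mid, 132 for Whole.

## Selection and classification

* **Relief** is the classic two-class algorithm (single nearest hit and
  miss, Euclidean distance on min-max-scaled features), run exhaustively
  over all instances by default — at these dataset sizes there is no reason
  to subsample, and exhaustive weights are permutation-invariant. Features
  with strictly positive weight are retained; if none is positive the single
  top-ranked feature is kept with a warning. ReliefF (k neighbours,
  multiclass) is deliberately not implemented.
* **SFS** is a greedy forward wrapper scored by stratified 10-fold
  cross-validated accuracy of the linear SVM on the training data; ties
  break to the lowest feature index; the search stops when no addition
  strictly improves the criterion, with no floor or ceiling on subset size.
* **SVM**: linear kernel, box constraint C = 1. "Auto kernel scale" is
  realized as per-training-fold z-score standardization feeding a
  scale-1 linear kernel — the equivalent operation for a linear SVM.
* **Nested CV**: stratified outer ten-fold partition (stratification
  prevents single-class folds at n = 20; plain random partitions are
  switchable and are redrawn until every training fold contains both
  classes). Accuracy is the mean of the ten held-out fold accuracies; F1,
  sensitivity, specificity and precision come from the fold-pooled
  confusion matrix with task as the positive class and 0/0 reported as 0.
* **Selection placement.** Whether the original selection ran once per
  dataset (leaking into test folds) or within training folds is not
  recoverable from the text. The default here is leakage-safe — selector
  and standardization are fitted per outer training fold — because that is
  the defensible inferential procedure. `paper_mode = TRUE` reproduces the
  apparent original order (selection once, before the partition); a test
  demonstrates that this mode is optimistic on permuted labels while the
  default stays at chance. The inner ten-fold loop tunes nothing (C is
  fixed), so it serves as the SFS criterion and is otherwise only reported.
* **Best-of-two**: per dataset the better of the Relief-fed and SFS-fed
  results is kept; ties go to the fewer-features outcome, then to Relief.

## Location statistics

Per location × window: mean, sample SD (n−1) and SE = SD/√n over subjects.
Each non-reference location is compared with Whole by a two-sided,
**pooled-variance** two-sample t-test at α = 0.05 with no multiplicity
correction, mirroring the original analysis. Pooled vs Welch is a
documented choice, not a stated fact: the description says only
"two-sample t-test", pooled is the common default of the original
implementation environment, and the Right/20 s contrast is borderline —
it flips under Welch, which the test suite records explicitly. The packaged
per-subject accuracy fixture recomputes every published summary row to
within one unit of the printed precision (the printed summaries were
evidently computed from unrounded per-subject values, so recomputation from
the 1-decimal table carries up to a double-rounding step of ~0.08) and
yields exactly four significant contrasts: Left at 5 s and Right at 5, 10
and 20 s. Every Mid contrast is non-significant — the result that motivates
a mid-forehead-only device.

## Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen as the smallest
sizes at which each property is meaningful: single-subject datasets of 3–10
sessions for pipeline mechanics; the chance-level property at 40 samples ×
8 features over 20 permutation seeds (≈800 pooled test predictions, giving
a ±3.5-point binomial interval around 50 %); and the location-ordering
property at one subject × ten sessions (the study's session count) at the
20 s window over six simulation seeds, where task/rest windows capture the
full hemodynamic plateau and accuracies sit in the high 90s as in the
published table. The full 240-dataset grid is enumerated and spot-run, not
exhaustively classified, in tests; `run_all()` executes it on demand.

## Known limitations

* Synthetic validation only: no deposited raw recordings exist, so
  full-pipeline accuracies are checked for qualitative structure (location
  ordering, chance behaviour, separability), not for numerical agreement
  with the published per-subject values.
* The SFS wrapper is O(p²) evaluator calls and each call trains ten SVMs;
  at 132 features it is the slow path. Relief is the practical default on
  wide matrices.
* The simulator's noise is stationary and sinusoidal; it does not model
  motion artifacts (screening reduces motion handling to a boolean flag) or
  short-separation channels, named as future directions in the original
  study and out of scope here.
* Appendix-level reproduction (raw feature values, per-dataset
  F1/sensitivity/specificity/precision tables) is out of scope: those data
  are not available in the source text, though the metrics themselves are
  computed for every fitted dataset.
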