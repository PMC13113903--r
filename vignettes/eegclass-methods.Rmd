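---
title: "Methods: modular EEG epoch classification with leakage-aware validation"
author: "eegclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular EEG epoch classification with leakage-aware validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegclass)
```

## The problem

Two-class classification of resting-state EEG — here, separating
schizophrenia patients from healthy controls — is usually run on short
epochs cut from each subject's recording. Because a subject contributes
many highly correlated epochs, any validation split that mixes one
subject's epochs across the train/test boundary lets a classifier learn
subject identity rather than disease physiology, and epoch-level accuracy
estimates become optimistic. This package implements the full pipeline —
preprocessing, tunable artifact removal, multiscale feature extraction,
minimum-redundancy–maximum-relevance (MRMR) selection, ensemble
classification — together with validation machinery that makes the
leakage measurable: the same configuration can be evaluated under
epoch-level k-fold and under leave-one-subject-out (LOSO), and the
accuracy gap between the two is itself a reported quantity.

## The synthetic cohort generator

Real cohorts in this field are small (tens of subjects) and access-gated,
so the package ships a generator that emulates their structure rather
than any individual recording. Per channel, a recording is

$$x(t) = \sum_{b \in \{\delta,\theta,\alpha,\beta\}} a_b \, m_b(\text{class}) \, g_{\text{subject}} \, s_b(t) \;+\; \varepsilon_{1/f}(t),$$

where each oscillation $s_b$ is band-limited Gaussian noise (white noise
put twice through a zero-phase 4th-order Butterworth bandpass, unit RMS)
rather than a pure sine, so
power spectra show broad band humps instead of degenerate line spectra;
$\varepsilon_{1/f}$ is $1/f^k$ background noise produced by spectral
shaping ($k = 1$, RMS 10 µV by default).

The tunable parameters and their defaults:

* `bandAmplitudes` (µV RMS): delta 20, theta 10, alpha 20, beta 5 — the
  usual resting-state ordering with a dominant posterior alpha.
* `patientMultipliers`: alpha 0.6, theta 1.4, others 1. The patient class
  shows reduced alpha and elevated theta power, the direction reported
  consistently for schizophrenia; 0.6/1.4 gives a clearly detectable but
  not trivial effect (about −1.0 on the log alpha-power scale).
* `subjectEffectSd`: log-scale SD of a log-normal gain drawn once per
  subject and applied to *all* bands and channels (default 0.2). This one
  knob creates the within-subject epoch correlation that makes epoch-level
  k-fold leak: with it at 0, epochs are exchangeable across subjects and
  the k-fold-vs-LOSO gap collapses to zero.
* `blinkRate`, `emgRate` (events/min): ocular artifacts are smooth ~100 µV
  Gaussian bumps (σ = 80 ms, energy almost entirely below 5 Hz) applied at
  full amplitude to channels whose 10–20 name starts with `F`/`Fp` and at
  20 % elsewhere; muscle bursts are 0.2–0.5 s high-passed (>20 Hz) noise
  bursts on a random channel. Event times are Poisson. The published
  cohorts' artifact content is uncharacterized, so these rates are test
  fixtures, not claims about the data; the defaults are 0.

Everything is deterministic given `seed`; per-subject and per-recording
seeds are derived arithmetically from it.

What the generator does *not* emulate: volume conduction and channel
covariance (channels are independent draws), nonstationarity within a
recording, medication or age effects, realistic electrode geometry.
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline machinery* is correct and that planted effects of realistic
size are recovered — not that any particular clinical accuracy would be
attained on real data.

## Preprocessing

Recordings are read from EDF (hand-validated 16-bit reader/writer; all
channels must share one sampling rate) or from concatenated text files
(all samples of channel 1, then channel 2, ...). Subject identity and
class labels come from a cohort manifest CSV, never from signal headers,
since neither source format carries reliable label metadata.

The bandpass is a 5th-order Butterworth applied forward–backward
(zero-phase), default 0.5–50 Hz; at that order the double pass pushes a
60 Hz line below 10 % amplitude while leaving the 0.5–50 Hz band flat
(order is configurable). Epochs are cut with window
`epochLen` = 6 s and `overlap` = 2 s by default, using 0-based half-open
sample intervals and dropping a trailing partial window:
$n_{\text{epochs}} = \lfloor (N - L)/S \rfloor + 1$ with
$L = \mathrm{round}(\text{epochLen} \cdot f_s)$ and
$S = \mathrm{round}((\text{epochLen} - \text{overlap}) \cdot f_s)$.
Published epoch totals for these cohorts are not all consistent with a
single epoching convention, so both values are exposed as configuration
rather than hard-coded. Optional per-epoch z-scoring normalizes each
channel within each epoch; constant channels are left unchanged so no
NaN can propagate.

## ATAR: tunable wavelet-packet artifact suppression

Each channel is processed in windows (default 6 s): a full wavelet-packet
decomposition (periodized Daubechies db4, depth 5 — reduced automatically
for short windows, padding by reflection to a multiple of $2^{\text{level}}$),
then every coefficient is compared against a data-driven threshold

$$\theta = \beta \,(k_1 + k_2\, \hat\sigma), \qquad
  \hat\sigma = \mathrm{IQR}(|w|)/1.349,$$

with defaults $k_1 = 1200$ µV and $k_2 = 10$. Smaller β means a lower
threshold and more aggressive suppression; the default β = 0.1 removes
blink-scale transients (coefficients of hundreds of µV) while leaving
ordinary oscillatory coefficients essentially untouched. Three attenuation
modes are provided: `elastic` (default) compresses magnitudes smoothly as
$\theta \tanh(|w|/\theta)$, `soft` clips magnitudes at $\theta$, and
`linear-attenuate` ramps coefficients linearly to zero at $2\theta$. All
three are non-expansive, so cleaning never adds energy, and the suppressed
energy is non-increasing in β — both properties are asserted by tests, as
is the recovery of a clean reference signal (relative RMSE ≤ 5 % at β ≥ 2)
and artifact-variance reduction against the generator's known clean
signal. The original description of this algorithm family publishes no
reference numerics, so the implementation is validated by these properties
rather than by numeric equivalence with any other code; all constants are
exposed in `atarParams()`.

Whether to clean the continuous recording or each epoch is configurable;
the default cleans the continuous recording before segmentation (method
dispatch on `EEGRecording` vs `EpochSet`). ICA is deliberately not
reimplemented — `artifact.method = "hook"` accepts any user function for
comparison studies.

## Features

Per epoch and channel, 21 features (so a 19-channel montage yields 399
columns, a 16-channel montage 336), named `CHANNEL__FEATURE`:

* 13 time-domain: mean, variance, SD, peak-to-peak, min, max, RMS, sum of
  absolute differences, skewness (Fisher–Pearson standardized third
  moment), excess kurtosis, and the Hjorth parameters — activity
  (variance), mobility $\sqrt{\mathrm{var}(\Delta x)/\mathrm{var}(x)}$,
  complexity $\mathrm{mobility}(\Delta x)/\mathrm{mobility}(x)$.
  A constant signal gets mobility = complexity = 0 by convention (0 rather
  than NaN so selection never sees missing values); a pure sinusoid has
  complexity ≈ 1.
* 8 frequency-domain, from a Welch PSD (Hann window, 1 s segments, 50 %
  overlap, per-segment mean detrend, one-sided density scaling — giving
  1 Hz resolution and ≥ 5 averaged segments per 6 s epoch): band powers
  (trapezoidal integral) for delta 0.5–4, theta 4–8, alpha 8–13, beta
  13–30 Hz; spectral entropy (base-2 Shannon entropy of the PSD normalized
  over 0.5–50 Hz, divided by $\log_2$ of the bin count, so 0 = spectral
  line, 1 = flat); and the mean, skewness and kurtosis of the PSD values
  over the same range. The delta band's edges and the PSD-moment domain
  are conventions chosen here (and configurable) since only the
  theta/alpha/beta ranges are fixed by common usage.

## Feature selection

The default chain is a low-variance filter (τ = 1e−10) followed by MRMR to
k = 50 features. Mutual information uses equal-frequency discretization
into 10 bins and the plug-in estimator in bits — simple, deterministic,
and invariant under monotone feature transforms. MRMR is the greedy MID
(difference) variant: the first pick maximizes MI with the label; each
subsequent pick maximizes relevance minus mean redundancy against the
already-selected set (MIQ available as a switch). Ties are broken by
ascending feature name so selections are identical across platforms.
Alternatives — MI ranking and recursive feature elimination dropping the
lowest-importance 10 % per random-forest round — are available in the same
chain syntax. All selectors run inside the training fold only; the
evaluation engine asserts this.

## Ensembles

Ten classifier families are registered (RBF-SVM, KNN, gradient boosting,
extra trees, random forest, decision tree, logistic regression, AdaBoost,
naive Bayes, MLP); the default ensemble combines RBF-SVM, KNN, gradient
boosting and extra trees by soft voting (weighted mean of member
probabilities, renormalized). Hard voting (weighted plurality; ties broken
by summed probabilities, then positive class) and stacking (logistic
meta-classifier on 5-fold cross-fitted member probabilities, members refit
on all rows) are alternatives. Scale-sensitive families (SVM, KNN,
logistic, MLP) receive train-fold standardized features; tree families see
raw features. Hyperparameters come from a randomized search (default 25
draws, stratified 5-fold accuracy within the training rows); the default
spaces are small published-practice grids (e.g. SVM C ∈ {0.1, 1, 10, 100},
γ ∈ {1/p, 0.001, 0.01, 0.1}) since no tuning grids are fixed by the
problem itself. Standard implementations supply the classifier internals
(e1071, ranger, xgboost, rpart, nnet, class, glm); AdaBoost is a compact
SAMME over rpart stumps implemented here. This module's own substance is
the orchestration: search, cross-fit plumbing, vote combination, and
seed discipline (every fit's seed derives from the run seed with
per-fold/per-model offsets).

## Validation and reporting

Fold plans: stratified random split (default 50/50), epoch-level k-fold,
and LOSO. For each fold the *entire* trainable pipeline — variance filter,
MRMR, standardization, tuning, ensemble — is fitted on the training rows
only; an audit log records the exact row sets consumed, and train/test
overlap anywhere is a hard error. Out-of-fold predictions are pooled;
epoch metrics (accuracy, per-class precision/recall/F1 with supports,
macro and support-weighted averages, confusion matrix, rank-statistic
ROC–AUC on the pooled probabilities — one pooled ROC rather than averaged
per-fold AUCs) and subject metrics are derived from the pool. The positive
class is `patient` throughout, so control recall doubles as specificity.

Subject aggregation uses the mean positive-class probability of each
subject's epochs, predicting patient at score ≥ 0.5 — deterministic under
ties and calibration-aware, in contrast to majority voting of hard labels.
The subject-level confidence interval is a percentile bootstrap
(default B = 2000, 95 %) resampling *subjects*, with inverse-ECDF
quantiles so the bounds are exact multiples of $100/n$ — on the grid the
underlying statistic actually lives on. The threshold sweep reports
precision/recall/F1 on a 0.001 grid and the smallest threshold attaining
the maximum F1. Paired per-fold comparisons use the two-sided Wilcoxon
signed-rank test (zero differences discarded; the reported W is the
smaller rank sum, so W = 0 when one arm wins every fold) with
Benjamini–Hochberg adjustment across the comparison family.

`leakageReport()` runs the identical configuration under epoch-level
k-fold and LOSO and reports both, plus the accuracy gap. On synthetic
cohorts the gap behaves as the leakage account predicts: zero (within
noise) when `subjectEffectSd = 0`, strictly positive and growing when
subject effects are present.

## Numerical choices and degenerate inputs

* Constant signals: Hjorth mobility/complexity 0, skewness/kurtosis 0,
  z-scoring skips the channel, variance filter removes the feature.
* Empty epochs: a recording shorter than one window yields an empty
  epoch set with a warning, not an error.
* Probabilities are clamped to [0, 1]; soft-vote rows renormalize to 1.
* All greedy/tuning ties break deterministically (feature name order;
  first-best hyperparameter draw).
* Seeds: one run seed; every stochastic stage uses a child seed derived
  by modular arithmetic, all below $2^{31}$.

## Simulation sizes used by the test suite

The bundled tests exercise the pipeline at desk scale: cohort-shape and
artifact checks on 1–28-subject cohorts of 2–60 s; planted-effect
recovery on 20 subjects per class (20 s, 4 channels); and the leakage
experiment on 12 subjects per class (60 s, 8 channels, 14 epochs/subject,
weak class effect — alpha ×0.9, theta ×1.1 — so neither scheme saturates),
with the MRMR panel at 30 and an untuned SVM + extra-trees soft vote.
These sizes recover all the planted effects while keeping the whole suite
runnable in minutes on one CPU; they are the package's own choices, and
nothing in the assertions depends on the specific cohorts beyond the
planted structure.

## Known limitations

* The synthetic channels are spatially independent; connectivity-based
  leakage or re-referencing questions cannot be studied with this
  generator.
* MRMR's MI estimator is the binned plug-in; numeric agreement with other
  MRMR tools (different estimators, variants) is not expected, only
  agreement with the criterion itself.
* The EDF writer emits one data record per recording with integer-µV
  physical bounds — correct and compact for fixtures, but not tuned for
  very long recordings.
* No ICA, no deep models, no SHAP (permutation importance over selected
  features can be computed from the fitted members, and the cleaning hook
  accepts external ICA implementations).
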