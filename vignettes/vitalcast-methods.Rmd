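---
title: "Methods: high-rate EWS and localized vital-sign forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-rate EWS and localized vital-sign forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalcast)
```

`vitalcast` analyses continuously monitored vital signs of hospitalised
patients along two tracks: a per-minute early-warning-score (EWS) component
stream, and a localized regression model that forecasts windowed vital-sign
statistics one to three hours ahead. This vignette documents the models,
their assumptions, the tunable parameters, and the numerical and design
choices, so that the package can be audited and adapted (e.g. to another
hospital's EWS standard) without reading the source.

## Signal model and conditioning

All channels — heart rate (BPM), respiration rate (BPM), systolic /
diastolic / mean arterial pressure (mmHg), oxygen saturation (%) — are
assumed to be resampled to a common 1 Hz grid before analysis.
`resample_uniform()` performs that unification by linear interpolation and
flags grid points inside input gaps wider than 5 s as low quality; gaps are
never interpolated across silently, and downstream segments touching
flagged samples carry `quality = FALSE` rather than being dropped, which
preserves temporal alignment.

Wearable-derived signals carry motion artefacts and estimation noise, so
each one-minute segment (60 samples) is denoised independently with a
fourth-order zero-phase Butterworth low-pass (`denoise_by_minute()`).
Parameters and defaults:

* `order = 4` — steep enough to separate minute-scale physiology from
  artefact energy without numerical fragility on 60-sample segments.
* `cutoff_hz = 0.035` — the midpoint of the 0.03–0.04 Hz range that is
  appropriate for these signals at 1 Hz; it is overridable per channel
  (`denoise_recording()` accepts a named list of `filter_spec()` objects).
* `zero_phase = TRUE` — the filter is applied forward and backward, which
  squares the magnitude response, `|H(f)|² = 1/(1 + (f/f_c)^8)` for the
  analog prototype, and cancels phase delay so segment statistics are not
  time-shifted.

Numerical contract of the filter: edges are handled by odd-reflection
padding of `3 × order` samples plus steady-state initial conditions for the
recursive pass. This makes a constant segment an exact fixed point (unit DC
gain to below 1e-6), keeps the operation exactly linear in its input, and
behaves sensibly on segments as short as one minute. Series shorter than
`3 × order + 1` samples are passed through unchanged with a warning rather
than filtered with meaningless transients. A trailing partial minute is
left unfiltered and flagged.

Whether per-minute denoising should filter each segment independently or
filter continuously and then segment is genuinely ambiguous; independent
per-segment filtering is the default and a `continuous = TRUE` flag
provides the alternative. A short spike is attenuated to roughly
`2 f_c × (spike area)` — e.g. a 3-s, ±30 BPM artefact leaves a bump of
about 6 BPM — which the test suite checks against that closed form.

## EWS component scoring

`ews_table` objects hold contiguous score bands (scores 0–3) per vital at a
printed resolution (1 unit for HR/RR/SBP/SpO2, 0.1 °C for temperature).
Two conventions make the printed table total over the reals:

* values are rounded half-up to the resolution before lookup, so a printed
  gap such as "40–50" next to "51–100" leaves no hole (50.4 → 50, 50.5 → 51);
* printed bands are closed intervals on the resolution grid, and where two
  printed bands share a boundary value the lower band wins (systolic 180
  scores 0, not 1).

The default table is the ZOL hospital standard (`zol_ews_table()`). Its
systolic row fills six printed bands left-to-right, leaving the
high-score-3 slot unused; the temperature row is shipped for completeness
but flagged `in_use = FALSE` because the targeted wearable measures no
temperature — scoring never exercises it. Any other hospital standard can
be loaded from YAML (`read_ews_table()`); the table validator enforces
contiguity, full coverage and the 0–3 score range.

`minute_ews_stream()` scores the min, max, mean and median of each denoised
one-minute segment independently; all four are reported because the
min–max spread within a segment is itself clinically informative.
`moving_median_score()` is the sliding variant (one-minute window, one-
sample step).

## Prediction instances

`build_instance()` turns a denoised recording into a regression example:
two overlapping one-hour windows ending at minute `t_end` — window A spans
minutes `[t_end−70, t_end−10)`, window B `[t_end−60, t_end)`, sharing 3000
of their 3600 samples — and, per window, 11 statistical features of each of
7 channels (HR, RR, SBP, DBP, MAP, SpO2, PP): min, max, mean, median,
standard deviation, variance and energy (sum of squares) of the denoised
signal, plus min, max, mean and standard deviation of its first difference.
The derivative's median, variance and energy are deliberately excluded: the
median and variance duplicate information already carried by the mean and
standard deviation at this window length, and derivative energy is
dominated by noise. That yields 77 features per window and 154 per
instance; `feature_grid()` documents the exact ordering and is the single
source of truth used by the naive baseline to locate window B's mean.

Targets are min / max / mean of the future one-hour windows at horizons
+1, +2, +3 h, where "+h" is the hour `[t_end+(h−1)·60, t_end+h·60)` —
horizon +1 starts immediately at `t_end`. Targets are computed on the
denoised series, consistent with how observed statistics are scored.
Instances are emitted every 10 min starting at `t_end = 70`, provided at
least one requested horizon's full hour fits inside the recording. For
short-stay profiles (dialysis, ~4 h sessions) the horizon set is `{1}`.

## The localized regressor

For each query the model is local: `knn_select()` finds the k nearest
training instances under a binary similarity criterion (weight 1 exactly
for instances within the k-th smallest distance, ties at that distance
broken by lowest row index), and `fit_ls_svm()` trains a least-squares SVM
on that neighbourhood only. The LS-SVM replaces inequality constraints and
ε-insensitive loss with equality constraints and squared error, so training
is one linear solve of

```
[[0, 1ᵀ], [1, Ω + I/γ]] [b; α] = [0; y],   Ωᵢⱼ = exp(−‖xᵢ−xⱼ‖² / (2σ₀²)),
```

with prediction `f(x) = Σ αᵢ k(x, xᵢ) + b` and residuals recoverable as
`αᵢ/γ`. With `k = N` (all weights 1) the localized model reduces exactly to
the global LS-SVM, which the test suite asserts to 1e-8; the dual solve is
also cross-checked against brute-force numerical minimization of the primal
objective on over a hundred random small problems.

Choices that the model's behaviour genuinely depends on:

* **Feature standardization** (`standardize = TRUE`, default): distances
  and kernels are computed after centring/scaling each feature by the
  training pool's location and scale. The raw features mix BPM, mmHg and
  energy scales spanning ten orders of magnitude; unscaled Euclidean
  distance would be dominated by the energy features.
* **Metric**: Euclidean by default; Mahalanobis (with a
  shrinkage-regularized pool covariance) and Chebyshev are available.
* **Neighbourhood size `k`**: 25 for the long-stay profiles
  (cardiology, postsurgical), 15 for dialysis, reflecting the smaller
  instance pool of short sessions.
* **`gamma`** (default 100) and **`sigma0`** (default `√d` on standardized
  features): the regularization/bandwidth pair; `tune_hyperparameters()`
  selects them by cross-validated mean absolute error over a grid
  (`default_grid()`: γ over decades 1–10⁴, σ₀ ∈ {0.5, 1, 2, 5, 10}·√d,
  k ∈ {5, 15, 25, 35}), with ties broken toward smaller k, then smaller γ.
* **Degenerate solves**: duplicate support points with extreme γ can make
  the dual system singular; it is then re-solved with a documented 1e-10
  ridge jitter and a warning.
* Each (vital, statistic, horizon) target is an independent scalar
  regression; no multi-output coupling is attempted.
* Neighbour search is exhaustive — pools here are at most tens of
  thousands of rows, where an index structure would not pay for itself.

## Evaluation protocol

`loio_evaluate()` is leave-one-instance-out: each instance in turn is
predicted from a pool of all remaining instances of all patients. The
held-out instance is removed from the pool before neighbour selection, so
it can never appear in its own neighbourhood. Instances of the same patient
(including temporally overlapping ones) remain in the pool — locality is
the point of the model, and neighbours are in practice a mix of same- and
other-patient instances.

The baseline, NaiveMean, forecasts every future mean as window B's mean —
persistence, read from the instance's own feature vector. Errors are
summarised as absolute error and MAPE
(`100 × mean(|truth − prediction| / |truth|)`, zero truths excluded with a
logged count; they cannot occur in physiological ranges). EWS-level
agreement uses the mean statistic of each scoreable vital (HR, SBP, SpO2,
RR — pulse pressure has no EWS row): predicted and true means are scored
and the normalized histogram of `|score(pred) − score(true)|` over {0,1,2,3}
is reported. Model-vs-naive significance uses a two-sided paired t-test on
absolute errors per vital and horizon (α = 0.01 by default); zero-variance
differences are reported as a degenerate case rather than an error.

## The synthetic cohort: what it emulates, and what it does not

Real recordings from the targeted wards are not redistributable, so
`generate_recording()` produces seeded stand-ins with the statistical
structure the analysis relies on:

* each channel follows a slow mean-reverting (Ornstein–Uhlenbeck) latent
  trend (stationary sd = `trend_amplitude`, correlation time
  `trend_timescale_s`, default 2 h) around a profile-specific baseline —
  smooth, stationary excursions of the kind per-minute trend scoring
  assumes;
* systolic pressure is built as diastolic + pulse pressure (both latent
  processes, pulse pressure floored at 5 mmHg), so SBP > DBP holds at every
  clean sample and MAP = DBP + (SBP − DBP)/3 exactly;
* measurement noise is white Gaussian per channel; motion artefacts are
  additive bursts of 5–30 s at a Poisson rate per hour with random sign and
  per-channel amplitude, recorded in a shared artefact mask;
* the dialysis profile adds a within-session linear systolic drift
  (−20 mmHg over the session by default), giving that profile its more
  dynamic pressure behaviour;
* profile durations default to 23 h (cardiology, postsurgical) and 4 h
  (dialysis); durations are parameters, not distributions, since only
  averages are known for the real wards.

`generate_learnable_cohort()` is the controlled variant used to demonstrate
forecasting skill: artefacts off, noise sd = trend amplitude / snr, 10
patients × 6 h by default (240 leave-one-out instances at horizon +1, which
comfortably exceeds the 200-instance floor the skill test requires; at
these sizes the full test suite runs in well under a minute). Under its 2-h
correlation time the next hour's mean is a smooth function of the preceding
70 min, so a model with any skill must beat persistence; the suite verifies
that the pooled correlation between consecutive window means exceeds 0.5,
that the localized model's mean absolute error is below the naive
baseline's for the +1 h mean of every channel, and that the paired t-tests
reach p < 0.01.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no circadian or treatment-driven structure, no
heavy-tailed or autocorrelated measurement noise, no sensor dropouts or
saturation artefacts beyond the burst model, no cross-channel physiological
coupling beyond the pressure identities, and no patient heterogeneity in
dynamics (profiles differ only in baselines, amplitudes and drift). Error
magnitudes obtained on synthetic cohorts therefore say nothing quantitative
about clinical performance; they demonstrate that the pipeline's machinery
— windowing, locality, evaluation — recovers predictable structure when it
exists.

## Seeding and determinism

Every stochastic component takes an explicit integer seed: one master seed
splits into per-patient streams (`seed + 7919·i` in the learnable cohort),
and identical seeds reproduce recordings bit for bit. Cross-validated
tuning seeds its fold assignment. Nothing in the package draws from the
global RNG state without setting it first.

## Known limitations

* The EWS output is per-component only; no aggregate score or
  alarm/escalation logic is provided (temperature and neurological
  responsiveness are unavailable from the device class targeted here).
* The per-segment filtering convention makes minute boundaries visible as
  (small) discontinuities in the denoised trace; use `continuous = TRUE`
  where a seamless trace matters.
* Leave-one-instance-out with same-patient instances in the pool is an
  optimistic protocol when instances overlap temporally; a stricter
  exclusion can be emulated by filtering the instance table before
  `loio_evaluate()`.
* Hyperparameter defaults are sensible for standardized features but are
  not universal; re-tune per deployment with `tune_hyperparameters()`.
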