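# vitalcast

Continuous vital-sign monitoring of hospitalised general-ward patients with
wearable sensors makes two things possible that routine nurse observations
(2–3 times a day) cannot deliver: a **per-minute early-warning-score (EWS)
component** for each vital sign, and a **short-horizon forecast (1–3 h) of
windowed vital-sign statistics**. `vitalcast` implements both analyses as a
tested, tidyverse-style R pipeline, together with a seeded synthetic cohort
generator so that every stage can be exercised end to end without access to
clinical data.

The pipeline covers heart rate (HR, BPM), respiration rate (RR, BPM),
systolic / diastolic / mean arterial blood pressure (SBP / DBP / MAP, mmHg),
oxygen saturation (SpO2, %) and the derived pulse pressure (PP = SBP − DBP),
all on a unified 1 Hz grid.

## What it computes

**High-rate EWS.** Each channel is denoised per one-minute segment with a
fourth-order zero-phase Butterworth low-pass (cut-off 0.035 Hz by default);
the segment statistics (min, max, mean, median) are scored 0–3 against a
hospital threshold table (the ZOL table ships as the default and is
hot-swappable via YAML). A moving-median variant slides the one-minute
window one sample at a time.

**Localized forecasting (kNN-LS-SVM).** Prediction instances are built every
10 min from the previous 70 min: two overlapping one-hour windows (50 min
overlap) × 7 channels × 11 statistical features per channel window
(min, max, mean, median, sd, variance, energy of the denoised signal; min,
max, mean, sd of its first difference). Targets are the min / max / mean of
the future one-hour windows at horizons +1, +2, +3 h. For each query
instance x_s, the k nearest training instances (binary similarity weights
λ(x_s, x_i) ∈ {0, 1}, k = 25 for cardiology/postsurgical, 15 for dialysis)
train a least-squares SVM

&nbsp;&nbsp;&nbsp;&nbsp;min_{w,b,e} ½‖w‖² + ½γ Σᵢ λ(x_s, xᵢ) eᵢ² &nbsp; s.t. &nbsp; yᵢ = wᵀφ(xᵢ) + b + eᵢ,

whose dual reduces to one linear system
`[[0, 1ᵀ], [1, Ω + I/γ]] [b; α] = [0; y]` with Gaussian kernel
Ωᵢⱼ = exp(−‖xᵢ−xⱼ‖²/(2σ₀²)); the prediction is f(x_s) = Σ αᵢ k(x_s, xᵢ) + b.
Evaluation is leave-one-instance-out against a naive persistence baseline
(NaiveMean: the previous hour's mean), with absolute error, MAPE, normalized
EWS-error histograms and paired t-tests.

## Worked example

```r
library(vitalcast)

score_component("SpO2", 89)   # 3  (below 91% scores the maximum component)
score_component("HR", 105)    # 1  (101-110 BPM band)

# per-minute EWS stream for one synthetic dialysis session
rec <- generate_recording(profile_spec("dialysis", duration_min = 240, seed = 7))
stream <- minute_ews_stream(rec$recording)
dplyr::filter(stream, vital == "HR", stat == "mean") |> head(4)
#>   segment_index channel vital stat  value score quality
#> 1             1 hr      HR    mean   79.4     0 TRUE
#> 2             2 hr      HR    mean   79.7     0 TRUE
#> 3             3 hr      HR    mean   81.0     0 TRUE
#> 4             4 hr      HR    mean   82.1     0 TRUE

# forecast skill on a small learnable synthetic cohort
cohort <- generate_learnable_cohort(4, snr = 5, seed = 7, duration_min = 240)
recs <- lapply(cohort, function(p) denoise_recording(p$recording))
instances <- cohort_instances(recs, horizons = 1)   # 48 instances
records <- loio_evaluate(instances, hyperparams(k = 15))
tidy(evaluation_report(records))
#>   vital statistic horizon     n mae_model mae_naive mape_model mape_naive
#> 1 HR    mean            1    48     0.596     2.20       0.743      2.75
#> 2 PP    mean            1    48     0.679     4.83       1.57      11.8
#> 3 RR    mean            1    48     0.232     1.78       1.37      10.0
#> 4 SBP   mean            1    48     0.874     5.00       0.789      4.69
#> 5 SpO2  mean            1    48     0.104     0.683      0.109      0.712
```

On this seeded cohort the localized model cuts the naive baseline's mean
absolute error by a factor of 3–7 on every channel
(`glance(evaluation_report(records))$all_significant` is `TRUE` at
α = 0.01). `plot_absolute_error(records)`, `plot_ews_error_histograms()`
and `plot_minute_scores()` draw the matching figures.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic cohort | `profile_spec()`, `generate_recording()`, `generate_cohort()`, `generate_learnable_cohort()`, `write_recording_csv()` |
| Signal conditioning | `filter_spec()`, `resample_uniform()`, `apply_zero_phase_lowpass()`, `denoise_by_minute()`, `denoise_recording()` |
| EWS scoring | `zol_ews_table()`, `ews_table()`, `score_component()`, `segment_statistics()`, `minute_ews_stream()`, `moving_median_score()` |
| Feature windows | `feature_grid()`, `extract_channel_features()`, `build_instance()`, `enumerate_instances()`, `cohort_instances()` |
| Localized regressor | `gaussian_kernel()`, `fit_ls_svm()`, `knn_select()`, `predict_local()`, `tune_hyperparameters()`, `hyperparams()` |
| Evaluation | `naive_predict_mean()`, `loio_evaluate()`, `mape()`, `ews_error_records()`, `ews_error_histogram()`, `paired_ttest_report()`, `evaluation_report()` |

The methods vignette (`vignettes/vitalcast-methods.Rmd`) documents the
models, the threshold-table conventions, the synthetic-data assumptions and
the numerical choices in detail.
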