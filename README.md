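# hrvdistf

Predicting ICU outcome from continuous heart rate variability (HRV)
monitoring with sliding-window Euclidean-distance features and
genetic-algorithm feature selection.

Severity scores such as APACHE II are computed once from admission
records, but the ECG is monitored continuously. This package implements a
pipeline that exploits that signal for binary outcome prediction
(survivor vs non-survivor):

1. **Per-epoch HRV parameters.** An RR-interval series is segmented into
   consecutive 30-minute epochs and 20 standard parameters are computed
   per epoch — time domain (HR, RR, SDNN, RMSSD, CVRR), Welch spectral
   (peak frequency, absolute power, relative power for the VLF/LF/HF
   bands, normalized units LFnu/HFnu, total power, LF/HF) and Poincaré
   (SD1, SD2).
2. **Distance features.** For each parameter *F* and time point *t*, the
   Euclidean norm over the following window of *n* = 8 epochs,

   DistF(t) = √(F(t)² + F(t+1)² + ⋯ + F(t+n−1)²),

   summarising the magnitude of the parameter's trajectory; a 48-epoch
   record yields 41 windows.
3. **Classification and selection.** A ridge-stabilised logistic model
   (penalty 1e-4) maps features to a probability of death; feature
   subsets are searched by a binary genetic algorithm whose fitness is
   the cross-validated **Youden index** J = sensitivity + specificity − 1
   at the 0.5 cutoff. Evaluation uses 5-repeated 5-fold **patient-grouped**
   cross-validation: each test fold holds 1 non-survivor and 4 survivors,
   each contributing 5 sampled time points (25 test rows), with all rows
   of test patients excluded from training.

A synthetic cohort generator with outcome-dependent autonomic spectral
structure (reduced/decaying LF and HF oscillations, truncated
non-survivor records, severity-score surrogates) makes the whole pipeline
testable without patient data. See the vignette
`vignettes/hrv-outcome-pipeline.Rmd` for the model details and design
choices.

## Worked example

```r
library(hrvdistf)

# one synthetic patient: 24 h of RR intervals
rr <- gen_rr_series(rr_gen_params(mean_rr = 950, lf_amp = 25, hf_amp = 35),
                    duration_hours = 24, seed = 7, patient_id = "demo")
rr
#> <rr_series> patient demo: 91142 beats, 24.00 h, mean RR 948.0 ms

ft <- compute_feature_table(rr)   # 48 rows x (patient_id, time_point, 20 parameters)
round(ft[1:3, c("time_point", "HR", "RR", "SDNN", "RMSSD", "LF_Hz", "HF_Hz", "LF_HF")], 2)
#>   time_point    HR     RR  SDNN RMSSD LF_Hz HF_Hz LF_HF
#> 1          1 61.59 975.80 39.48 49.53   0.1  0.24  0.55
#> 2          2 61.32 980.12 39.31 49.70   0.1  0.24  0.50
#> 3          3 61.15 982.83 39.54 50.29   0.1  0.24  0.46

d <- sliding_dist(ft)             # 41 rows of Dist* features
round(d[1:2, c("time_point", "window_start", "window_end", "DistHR", "DistRR")], 1)
#>   time_point window_start window_end DistHR DistRR
#> 1          1            1          8  172.7 2783.3
#> 2          2            2          9  172.5 2787.3
```

The per-epoch values behave as the generator dictates: HR near
60000/950 bpm, the LF and HF spectral peaks at the configured 0.1 and
0.25 Hz, and LF/HF below 1 because the HF amplitude (35 ms) exceeds the
LF amplitude (25 ms). `DistHR` ≈ 61·√8 because HR is nearly constant
across the window.

Comparing models on a full synthetic cohort (26 patients, 21/5 outcome
split, shared folds):

```r
co    <- gen_cohort(cohort_config(record_hours = 12, seed = 1))
folds <- make_folds(co, cv_scheme(seed = 1))
tab   <- compare_models(list(apache = "APACHE_II",
                             distf = c("DistRMSSD", "DistHF_ms_sq", "DistSDNN")),
                        co, folds)
writeLines(format_report(tab))
```

| Set | Features | Train AUC | Test AUC | Test Sens | Test Spec |
|---|---|---|---|---|---|
| apache | APACHE_II | 0.74 [0.69, 0.79] | 0.76 [0.58, 0.94] | 0.00 [0.00, 0.00] | 0.97 [0.94, 1.00] |
| distf | DistRMSSD + DistHF_ms_sq + DistSDNN | 1.00 [1.00, 1.00] | 1.00 [1.00, 1.00] | 1.00 [1.00, 1.00] | 1.00 [1.00, 1.00] |

The severity-score surrogate discriminates at AUC ≈ 0.75 but, at the 0.5
cutoff, almost never calls a non-survivor (sensitivity 0 with high
specificity) — the classic behaviour of a weakly shifted continuous
score. The distance features separate the groups completely here because
the default generator effects are strong; the calibration and recovery
experiments in the test suite probe the regimes in between.

Feature selection with the GA:

```r
sel <- ga_select(co, paste0("Dist", hrv_feature_names()), folds,
                 ga_config(population_size = 30, n_generations = 40,
                           n_runs = 5, seed = 1))
sel$final_feature_set
```

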