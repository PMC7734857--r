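---
title: "Predicting ICU outcome from sliding-window HRV distance features"
author: "hrvdistf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ICU outcome from sliding-window HRV distance features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuously monitored ECG is a standard of care in intensive care, and
heart rate variability (HRV) — the beat-to-beat variation of the RR
interval — carries information about autonomic regulation that illness
severity scores computed once at admission cannot. This package implements
a pipeline that turns a patient's RR-interval record into a mortality
prediction:

1. **Per-epoch HRV parameters.** The record is cut into consecutive
   30-minute epochs and 20 standard parameters are computed per epoch:
   time domain (HR, mean RR, SDNN, RMSSD, CVRR), frequency domain (peak
   frequency, absolute power, relative power in the VLF/LF/HF bands,
   normalized units, total power, LF/HF ratio) and the Poincaré
   dispersions SD1/SD2.
2. **Sliding-window distance features.** For each parameter, the
   Euclidean norm of a window of `n = 8` consecutive epoch values,
   `DistF = sqrt(F1^2 + ... + Fn^2)`, indexed by the window's first time
   point. A 48-epoch (24-hour) record yields 41 such windows.
3. **Classification and feature selection.** A ridge-stabilised logistic
   model maps feature vectors (HRV parameters at a time point, distance
   features at the same index, and/or severity scores) to a probability
   of death, with subsets searched by a genetic algorithm whose fitness
   is the cross-validated Youden index, under repeated patient-grouped
   five-fold cross-validation.

Because no public dataset accompanies this design, the package includes a
first-class synthetic cohort generator so that every stage is testable,
and so that statistical claims (calibration under the null, recovery of
planted signal, ranking of feature families) can be verified end to end.

## Spectral estimation choices

Spectral parameters need a uniformly sampled signal, so each epoch's
tachogram RR(t) (interval value at its beat onset time) is cubic-spline
interpolated onto a 4 Hz grid, linearly detrended, and passed to a Welch
estimator (256-s Hann segments, 50% overlap). Band limits follow the
short-term standard: VLF [0, 0.04), LF [0.04, 0.15), HF [0.15, 0.4] Hz.
Defaults and rationale:

* **4 Hz resampling** puts the Nyquist frequency at 2 Hz, far above the
  0.4 Hz upper HF edge, and is the conventional tachogram rate.
* **Linear detrending** is a deliberate, simple choice (smoothness-priors
  detrending is a common alternative in commercial HRV software); it is
  configurable via the `detrend` argument.
* **Total power** is the integral of the full one-sided PSD, so it obeys
  Parseval's identity against the detrended tachogram variance (tested to
  within 15%). Because broadband noise puts some power above 0.4 Hz, the
  three band percentages sum to slightly less than 100.
* **Normalized units** divide LF and HF by the *in-band* total minus VLF,
  i.e. by LF + HF, so `LF_nu + HF_nu = 100` exactly. Had the full-spectrum
  total been used, the identity would fail by the above-band noise share;
  the in-band convention matches how normalized units are reported in
  practice.
* **HR** is the mean of per-beat instantaneous rates 60000/RR; the
  alternative 60000/mean(RR) is available via `hr_method`.
* **SDNN** uses the sample (n−1) denominator. SD1/SD2 are computed from
  the identities SD1² = SDSD²/2 and SD2² = 2·SDNN² − SDSD²/2 (the SD2
  radicand clamps at zero), which makes SD1² + SD2² = 2·SDNN² exact.

Epochs too short or sparse for a given analysis (fewer than 2 beats for
time domain, 3 for Poincaré, 4 beats or under 60 s span for spectra)
yield missing values in the affected columns; rows are never dropped, so
time-point indices stay aligned with wall-clock time. Distance-feature
windows containing missing values propagate the missingness rather than
shrinking the window.

## Distance features

`dist_feature()` applies no normalisation before the norm: the feature is
deliberately scale-dependent (an HR window and an RR window live on very
different scales), which reproduces how the windowed norms behave on raw
parameter tables. An optional z-scoring switch exists in the modelling
layer (`standardize` in `fit_logistic()`), off by default. The window
length 8 is chosen so that even records truncated to a few hours (a
patient who dies early) still contribute windows; it is configurable for
longer records.

## Cross-validation protocol

`make_folds()` implements repeated (default 5×) five-fold CV with the
fold composition the analysis is designed around: each test fold holds
exactly 1 non-survivor and 20% (rounded down: 4 of 21) of the survivors,
each contributing 5 randomly drawn time points with a complete following
window — 25 test rows per fold. Splits are **by patient**: all rows of a
test patient are excluded from that fold's training data, because
time-point rows of one patient are strongly dependent and splitting them
across train and test would leak identity information and inflate test
performance. A literal variant that keeps the unselected rows of test
patients in training (`include_test_rows_in_train = TRUE`) is provided
for comparison. The same fold object must be reused across all compared
models; `compare_models()` enforces this by construction.

Metrics per (repeat, fold) cell: Mann–Whitney AUC, and sensitivity /
specificity at the probability cutoff 0.5 with a *strict* inequality
(exactly 0.5 classifies negative). The positive class is non-survival
throughout. Aggregates are the mean over the 25 cells with a 95%
confidence interval whose standard error is computed over per-cluster
means, clustering cells on the identity of the fold's test non-survivor
(t quantile over the ~5 cluster means). The clustering matters: cells
that test the same non-survivor are strongly dependent, and the naive
per-cell SE undercovers badly — in the null-calibration experiment below
its CI contained 0.5 in only 65% of null cohorts, against 95% for the
clustered interval. The naive method is retained as
`ci_method = "normal"` for comparison with reports that use it.

## Logistic model

`fit_logistic()` is IRLS with a quadratic penalty `0.5·λ·Σβ²` (λ = 1e-4,
intercept unpenalised). With 5 positive patients per cohort, perfectly
separable training folds are routine and unpenalised ML diverges; the
tiny ridge keeps fits finite and is far too small to move
well-conditioned estimates (tested against `glm` and against a
brute-force penalised-likelihood grid search). Features enter raw, with
optional training-fold z-scoring.

## Genetic algorithm

`ga_select()` searches binary feature masks with a conventional small GA:
tournament selection (size 3), uniform crossover (rate 0.8), per-bit
mutation (rate 1/L), elitism (2), population 50, 100 generations by
default — all configurable, as none of these internals is prescribed by
the protocol the package implements. Fitness is the mean per-fold Youden
index of a ridge-logistic fit on fixed, shared folds; the per-fold design
matrices over the full candidate set are assembled once and each
chromosome evaluation selects columns, with memoisation across
evaluations and runs.

Two aggregation details deserve comment:

* **Parsimony tie-break.** Youden's J on 25-row test folds is coarsely
  quantised, so many masks can tie at the optimum; during selection a
  penalty of 1e-4 per selected feature breaks these ties towards smaller
  sets without ever trading away a real fitness difference (J moves in
  steps orders of magnitude larger). Reported fitness excludes the
  penalty; set `parsimony = 0` to disable.
* **Across-run aggregation.** The search restarts `n_runs` times from
  different seeds; a feature enters the final set when it appears in more
  than half (configurable) of the per-run best chromosomes, with ties
  broken towards features whose containing runs scored higher. If no
  feature clears the threshold, the single most frequent feature is
  returned so the final set is never empty.

## The synthetic cohort generator

`gen_rr_series()` models an RR record as a sum of interpretable
components around a constant mean: an LF oscillation (~0.1 Hz, baroreflex
range), an HF oscillation (~0.25 Hz, respiratory range), a 24-h-period
drift (centred over the record so the realised mean RR is unbiased even
for short records), and per-beat Gaussian broadband noise; an optional
per-hour multiplicative decay shrinks the oscillations and noise over
time, emulating progressive autonomic failure. Components are evaluated
at nominal beat times `k·mean_rr`; the realised beat times are the
cumulative interval sums. The first-order frequency distortion of this
shortcut is O(Δrr/mean_rr) — a few percent at most, well inside the band
limits — and it makes generation fully vectorised (a 24-h record in
~30 ms). Intervals clip at 250 ms.

`gen_cohort()` draws per-patient parameters from between-patient
distributions and applies outcome effects. The default configuration *is*
the study condition the pipeline targets: 26 patients (21 survivors, 5
non-survivors), 24-h records, 30-min epochs, window 8, two non-survivors
truncated to 6–12 h. The truncation floor of 6 h guarantees every patient
at least 12 epochs and hence 5 complete windows, so the 25-row fold
arithmetic holds for every fold; shorter records (down to the window
length) are supported and handled by sampling fewer time points with a
warning. Two between-patient correlation structures are modelled because
real cohorts have them: a lognormal *autonomic tone* factor multiplying
the LF/HF amplitudes (and optionally the noise SD), and a lognormal
*pacing* factor multiplying both oscillation frequencies (respiratory and
baroreflex rhythms co-vary). Severity-score surrogates (APACHE II/III,
SAPS) are Gaussian with group-shifted means tuned so the score-only
discrimination sits near AUC 0.7; they are opaque covariates, not
re-implementations of the clinical scores.

Default non-survivor effects encode the regime the analysis is built for:
reduced oscillatory and broadband variability (multipliers 0.6/0.5/0.6)
with a 3%-per-hour decay. What the generator does **not** emulate:
ectopy and artifacts, non-stationary interventions (medication boluses,
ventilation changes), realistic ECG morphology, or any claim about actual
TBI physiology. Passing tests therefore demonstrate correctness and
statistical sanity of the *pipeline*, not clinical performance on real
patients.

## Verification experiments and problem sizes

The acceptance suite (in `tests/testthat/test-acceptance.R`, recomputed
by `scripts/acceptance.R`) runs:

* the two worked-example window norms of the one-patient data-structure
  table (166.9 and 2884.1, to one decimal);
* structural bookkeeping on the default 24-h cohort (48 epochs → 41
  windows; 26 patients 21/5; 25 folds of 25 test rows);
* spectral/Poincaré oracles (Parseval within 15% over 20 random epochs,
  `LF_nu + HF_nu = 100`, SD1²+SD2² = 2·SDNN², single tones localised to
  their bands);
* AUC/Youden against exhaustive pair counting and blind-rule values;
* **planted-signal recovery**: 20 cohorts in which non-survivors carry
  opposite-signed shifts of the two oscillation peak frequencies
  (LF +0.015 Hz, HF −0.05 Hz) under a strong shared pacing factor
  (`freq_scale_sd = 0.15`). Each peak-frequency distance feature alone is
  confounded by the shared factor (per-fold J typically 0–0.7) while the
  pair cancels it (J ≈ 1), and no other candidate depends on oscillation
  frequency, so exactly two of the ten candidates carry the signal. The
  GA (population 30, 40 generations, 3 runs, Youden fitness on 15 shared
  folds) must return both planted features in at least 80% of cohorts.
  This design was chosen over amplitude-multiplier effects after the
  latter proved unidentifiable: any band-amplitude change leaks into
  SDNN, RMSSD, the Poincaré measures and the power ratios, so no
  candidate list of real features contains "exactly two" signal carriers,
  and a correct selector then legitimately substitutes correlated
  features. RMSSD-family features are excluded from the candidate list
  here because the successive-difference filter gain depends on the HF
  frequency;
* **null calibration**: 20 null cohorts (all effects off) — mean test AUC
  of the distance-feature model within [0.4, 0.6] and the 95% CI covering
  0.5 in ≥ 90% of runs;
* **directional comparison**: 20 default-effect cohorts — the
  distance-feature set beats the severity-score baseline's test AUC in
  ≥ 80% of runs, the qualitative headline the pipeline is designed to
  support.

Experiment problem sizes are the package's own choices: the recovery and
calibration experiments use 8–12-h records (16–24 epochs per patient)
rather than 24 h, because the group structure is stationary within a
record and the extra epochs only add compute; the bookkeeping checks use
the full default 24-h cohort. GA experiments use the reduced budget
(population 30, 40 generations) at which the landscape above is already
searched essentially exhaustively for 10 candidates.

## Known limitations

* Exact numeric agreement with any particular commercial HRV package is
  not claimable: detrending method, interpolation and FFT segmentation
  conventions differ between implementations and are rarely documented.
* The Welch peak-frequency estimate is quantised at the bin width
  (4/1024 ≈ 0.004 Hz), which is visible in the distance features of the
  peak-frequency columns.
* The CI method over fold-level metrics treats cells as independent,
  which repeats violate mildly; the CIs are calibrated in the null
  experiment but remain approximations.
* With 5 positive patients, fold-level metrics are coarse; conclusions
  from any single 26-patient cohort — real or synthetic — carry wide
  uncertainty, which is precisely why the acceptance experiments repeat
  over 20 generated cohorts.
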