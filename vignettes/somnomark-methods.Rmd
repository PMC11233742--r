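---
title: "From overnight polysomnography to CSF biomarker estimates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From overnight polysomnography to CSF biomarker estimates: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lumbar puncture is the reference route to the cerebrospinal-fluid (CSF)
Alzheimer core biomarkers --- amyloid-beta 1-42 (Abeta42), phosphorylated tau
(p-tau) and total tau (t-tau), all in pg/ml --- but it is invasive and poorly
suited to repeated monitoring. Sleep physiology degrades early in Alzheimer's
disease, and overnight polysomnography (PSG) is routine, non-invasive and
information-rich. `somnomark` implements a complete measurement-and-modelling
chain that asks how much of the CSF biomarker signal can be recovered from a
single PSG night: signal preprocessing, quantitative feature extraction,
conventional sleep-parameter derivation, statistically disciplined feature
selection, and a benchmark of fifteen classical regression models scored by
mean absolute error (MAE, pg/ml).

Biomarker positivity conventions are housed as constants
(`biomarker_cutoffs()`): Abeta42 below 600 pg/ml indicates amyloid
deposition; t-tau above 425 and p-tau above 65 pg/ml indicate neurofibrillary
tangles.

## Preprocessing

Each channel kind carries a filter specification
(`default_filter_table()`): a harmonized target rate `fst`, a spectral output
rate `fsf`, and a fifth-order Butterworth band. EOG/EEG run at 500/500 Hz
with 0.3--50 Hz; EMG at 500/200 Hz with 1--90 Hz; airflow at 100 Hz with
0.1--15 Hz; ECG at 500/200 Hz with 0.3--50 Hz; snore at 500 Hz with
1--100 Hz; effort, pulse and SpO2 pass unfiltered. Leg channels are absent
from the standard montage table; the shipped default treats them like EMG
(they are surface EMG over the tibialis), and any kind without a row is a
configuration error.

Design choices that were genuinely open:

* **Two analysis streams.** The time-domain and non-linear features are
  computed on a common 128 Hz stream (comparable complexity estimates across
  channels), while spectral features are computed at each kind's `fsf`
  (the Welch window sizes only make sense at those rates). Both streams are
  carried through stage decomposition and artifact exclusion in parallel.
* **Order of operations.** Resample, then filter, then decompose by sleep
  stage, then drop artifact segments. Filtering the continuous record before
  concatenation avoids filter transients at the joints between
  non-contiguous same-stage epochs; the joints are nevertheless recorded
  (`joint_offsets`) so window placement can be audited.
* **Zero-phase filtering.** The Butterworth design is applied
  forward-backward (`signal::filtfilt`), so stage-dependent phase distortion
  cannot leak into skewness or entropy estimates. The "fifth-order" design
  is honoured per pass. The signal mean is removed before filtering: with a
  0.3 Hz low edge at 500 Hz the discretized transfer function's DC response
  is dominated by a slow edge transient, and explicit centering removes the
  offset exactly (verified: passband gain 1.00 at 10 Hz, 2e-5 at 0.1 Hz).
* **Resampling.** Rational-factor polyphase resampling with a windowed-sinc
  FIR (Hamming, 20 taps per phase, cutoff at the lower of the two Nyquist
  limits), delay-compensated. This attenuates the folded image of a 60 Hz
  tone in a 500 to 100 Hz conversion by ~48 dB, versus ~6 dB for naive
  decimation. Linear interpolation is reserved for the 1 Hz oximetry and
  pulse channels, where a step-wise signal makes sinc interpolation
  meaningless.
* **Artifact grid.** The concatenated per-stage signal is cut into 10-s
  segments (incomplete tails dropped); a segment is excluded if its *source*
  time range overlaps an annotated artifact for that channel or for `"*"`,
  by any amount. Because scoring epochs are 30 s, segments never straddle
  epochs and the source mapping is exact.

## Feature extraction

Features are computed in 2-minute windows with 50% overlap
(`n = floor((T - 120)/60) + 1` windows for a stage of `T` seconds) and
averaged per sleep stage; a stage shorter than one window yields missing
values. Names follow `{channel}_{code}_{stage}`, e.g. `EEGO1_A2_sk_N1`.

* Time domain: RMS, population variance, skewness, kurtosis (raw, not
  excess: Gaussian windows sit near 3), maximum. Zero-variance windows set
  skewness and kurtosis to 0 by convention.
* Non-linear, with defaults chosen where the field has conventions and
  recorded in `nonlinear_params()`:
  * Sample entropy, `m = 2`, `r = 0.2` of the window SD, Chebyshev distance,
    self-matches excluded. The implementation enumerates template pairs by
    lag with a run-length scan (exact, O(N^2), sequential memory access) and
    is verified against an exhaustive brute-force oracle. Its cost is
    quadratic in the window length (15,360 samples at 128 Hz), so an
    optional decimation factor exists (`sampen_decimate`, default 1 = none);
    whenever a run uses it, the factor is part of the run configuration and
    recorded in the run log.
  * Shannon entropy of a 16-bin equal-width amplitude histogram, in bits.
  * Lempel-Ziv: binarize at the window median, LZ76 exhaustive-history
    parsing, normalized `c(n) log2(n) / n` (about 1 for random sequences).
  * Higuchi fractal dimension with `kmax = 10`; reported value clipped to
    [1, 2] with the raw slope retained as an attribute.
* Spectral (EOG, EEG, EMG, airflow, SpO2 only): Welch's averaged modified
  periodogram of the z-scored window, Hamming taper, 50% segment overlap,
  zero-padding to the per-kind FFT length (65,536 EOG; 32,768 EMG; 16,384
  airflow; 128 SpO2). The EEG length is not specified by the AASM-style
  table we follow; EEG shares the EOG filter band and 500 Hz rate, so it
  uses the EOG value. Stated FFT lengths exceed a 2-min window at some
  rates; they are therefore read as the zero-padded FFT size with segment
  length `min(window, nfft)` --- the only reading that keeps 2-minute windows
  meaningful. Band powers are trapezoidal integrals of the one-sided
  density (EEG sub-bands: delta 0.5--4, theta 4--7, alpha 8--12, lowBeta
  14--22, highBeta 23--30, beta 14--30, gamma 31--40, spindle 12--14 Hz);
  `DF` is the in-band peak frequency and `MF` the median (half-power)
  frequency --- both defined here explicitly since "median" and "dominant"
  frequency admit variants. Powers are those of the normalized window and
  are dimensionless by construction.

Wake epochs are discarded throughout; a configuration flag could re-admit
them but the default pipeline never computes wake features.

## Conventional sleep parameters

`derive_sleep_parameters()` consumes the hypnogram, scored respiratory
events, arousal intervals and the SpO2 trace: TIB (the full recording span;
lights-off markers are not modelled), TST, SE = 100 TST/TIB, AI and AHI per
hour of TST, per-kind apnea sub-indices, ODI (events flagged with a >= 3%
desaturation), CT90 (percentage of sleep time with SpO2 < 90%), stage times,
percentages and latencies, and an OSA flag that is *strictly* AHI > 15 (an
AHI of exactly 15.0 is not flagged). Event *detection* from the airflow
trace exists as an optional helper (`detect_respiratory_events()`), but the
pipeline consumes expert annotations --- detection quality is not allowed to
contaminate the sleep-parameter block.

## Feature selection

Per target biomarker (`build_subsets()`), on one shared train/test split:

1. split subjects once, `round(n * 0.25)` to the test side, seeded;
2. drop features missing in more than 50% of samples (strictly more);
3. keep features whose training-rows Pearson correlation with the target
   reaches |r| >= 0.1 (clinical and conventional-PSG subsets) or exceeds
   |r| > 0.3 (signal-feature subset); binary variables enter as 0/1;
4. form ALL as the union of the three screened sets;
5. prune redundancy: order by decreasing |target correlation| (ties
   lexicographic), drop a feature whose |r| with any retained feature
   exceeds 0.9 --- the surviving member of a redundant pair is the one more
   strongly tied to the target;
6. z-score with training mean/SD, applied unchanged to test rows;
7. PCA fitted on training rows; keep the smallest component count whose
   cumulative explained variance reaches 90%; `pca_sel` is, per retained
   component, the feature with the largest absolute loading.

Features that still contain missing values after the screens are dropped
with a warning: imputation is deliberately out of scope, and silently
mean-filling would blur the leak-free guarantee that every train-fitted
statistic can be reproduced bit-exactly from training rows alone (a property
the test suite asserts).

Screens are re-run per biomarker, which is why the selected variable lists
differ across targets.

## The model zoo

Fifteen classical regressors in five families (`model_zoo()`): bagging
ensembles (Bagging Regressor as a random forest with `mtry = p`, Extra
Trees, Random Forest; 500 trees), three gradient-boosting regressors
distinguished by loss (least squares, least absolute deviation, Huber with
the transition at 1.35 robust SDs of the target), Ridge and Lasso, Gaussian
processes with RBF and Matern 3/2 kernels, k-nearest-neighbour regression,
and support vector regression with linear, polynomial, RBF and sigmoid
kernels. Hyperparameter grids are small and documented in the function
reference; every grid is resolved by 5-fold cross-validation minimizing mean
out-of-fold MAE, refitting the winner on the full training partition. The
GP models have no grid: their kernel hyperparameters are optimized by
maximum marginal likelihood from 20 seeded log-uniform restarts, keeping the
best objective --- the restart protocol replaces the grid. The GP is
implemented in-package (exact GP with a noise term) because no installed
kernel library offers Matern 3/2 with a restart protocol; its predictions
are exercised against interpolation sanity checks in the suite.

All models are trained on PCA scores, with one deliberate exception: the Bagging Regressor is *additionally* trained on the raw
standardized features named by `pca_sel` (rows tagged `BR_pca_sel`, no
family). Family aggregates (mean +- SD of member-model MAEs) are computed
over the fifteen core models; the single-member KNR family reports no SD.
Aggregation across family members, not CV folds, is what makes a
single-member family SD-less --- the alternative reading would give every
family an SD.

Determinism: every stochastic fitter receives a seed derived from the run
seed and the cell coordinates (`derive_seed`), `xgboost` and `ranger` run
single-threaded, and re-running any cell reproduces it bit-identically.

## The synthetic cohort generator

No patient recordings ship with the package; the generator produces the
statistical structure the analysis assumes, at two fidelities:

* **Signal mode** synthesizes the nine-channel montage per subject: 1/f EEG
  background with stage-gated content (slow waves in N3, Poisson spindle
  bursts at 12--14 Hz in N2, theta in REM, alpha in wake), EMG amplitude
  decreasing from wake to N3 and minimal in REM, ~0.25 Hz respiration on
  effort and airflow with planted apneas (airflow x0.1, duration 11--25 s)
  and hypopneas (x0.7), SpO2 desaturations of 3--6% following flagged
  events, ECG and snore filler channels, and global artifact intervals.
  Hypnograms are first-order Markov chains whose default transition matrix
  yields fragmented, N2-dominated sleep as seen in elderly cohorts with
  dementia and a high prevalence of sleep apnea (default planted rates:
  27 respiratory events and 36 arousals per hour of sleep, matching the
  intended cohort's medians). Planted events are returned as ground truth,
  so every derived sleep parameter can be checked for exact closure.
* **Feature mode** draws the clinical, sleep-parameter and signal-feature
  tables directly from cohort-level distributions (a two-factor latent
  structure for the signal features). This is the fast path for
  selection/model studies at n = 300.

Biomarkers are drawn from marginals calibrated to the intended cohort:
Abeta42 as a truncated normal (median 515 pg/ml, SD 155 matched to the
interquartile width), p-tau and t-tau as right-skewed lognormals (medians
82 and 555 pg/ml; log-SDs 0.476 and 0.576 matched to the reported IQRs).
Feature-biomarker couplings are planted through a Gaussian copula: plan
features are rank-transformed to normal scores, latent weights solve
`C w = rho`, and the latent draw is pushed through the marginal quantile
function. A skewed marginal attenuates Pearson correlation relative to the
latent scale by the deterministic factor `cor(Z, q(pnorm(Z)))` (~0.92 for
the t-tau marginal), so latent targets are inflated by that factor --- the
realized Pearson r then lands on the planted value (0.42 +- 0.05 at
n = 300). Plans whose implied latent variance reaches 1 are rejected before
generation.

What the generator does **not** emulate --- and hence what passing tests do
not show about real data: real EEG microstructure (K-complexes, arousals
visible in EEG, topography), realistic ECG morphology, body position,
scorer disagreement, device drift, and above all a *true* physiological
link between sleep physiology and CSF biology. Planted correlations
demonstrate that the pipeline recovers effects of the stated size at the
stated n; they say nothing about whether such effects exist in patients.

## Numerical choices and degenerate inputs

* Quartiles are type-7 (linear interpolation); the descriptive formatter
  gates mean (SD) versus median [q1; q3] on Shapiro-Wilk at alpha 0.05 and
  accepts an explicit override, since small regular samples (e.g. 1..9) are
  not rejected by any normality test yet may be better served by quartiles.
* No multiple-testing correction is applied to the association tables, which
  mirror a screening (not confirmatory) use; a Benjamini-Hochberg column is
  emitted alongside, clearly supplementary.
* Degenerate windows: constant windows give Shannon entropy 0, skewness and
  kurtosis 0, missing sample entropy and missing Higuchi dimension; sample
  entropy is missing whenever either template count is zero.
* EDF storage is 16-bit with per-channel physical calibration; calibration
  values are round-tripped through their ASCII header representation before
  quantization, keeping read(write(x)) within one quantization step.
* Ties in the CV grid resolve to the first row in grid order; ties in the
  redundancy pruning resolve lexicographically. Both are frozen so reruns
  are bit-identical.
* Run artifacts are checksummed (MD5) and two runs with the same seed are
  byte-identical over all tabular/JSON/log outputs; figures (PNG) are
  excluded from the manifest because image encoding is library-dependent.

## Problem sizes used by the shipped tests

The suite exercises the full chain at sizes chosen to be representative yet
desk-scale: single nights of 2--20 minutes for signal-level checks, the
61-subject recruitment structure (3 missing PSG, 9 missing biomarkers,
49 analyzable) for cohort logic, n = 300 feature-mode cohorts for planted
effect recovery, n = 200 planted-linear regression for near-Bayes MAE
checks, and a 20-subject, 20-minute-night end-to-end demonstration run
twice to assert byte-identical reproduction. The demo uses the documented
sample-entropy decimation factor 2; all other analyses run undecimated.

## Known limitations

* The GP implementation is exact (O(n^3)); it is intended for the small-n
  regimes this analysis targets, not for thousands of subjects.
* The EDF writer requires integer sampling rates and whole-second records
  (1-s EDF data records); EDF+ annotation channels are not parsed.
* Hypnograms are consumed, never produced: there is no automatic sleep
  stager, and no automatic artifact detector beyond the optional
  respiratory-event helper.
* With 2-minute windows, stages shorter than two minutes contribute no
  features --- short fragmented stages (common in short test nights) are
  systematically under-represented, which is faithful to the windowing rule
  but worth remembering when interpreting missing-feature patterns.
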