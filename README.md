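# somnomark

Non-invasive estimation of the cerebrospinal-fluid (CSF) Alzheimer core
biomarkers — amyloid-beta 1-42 (Aβ42), phosphorylated tau (p-tau) and total
tau (t-tau), in pg/ml — from overnight polysomnography (PSG).

Lumbar puncture is the reference route to these biomarkers but is invasive
and hard to repeat; a PSG night is routine and information-rich. `somnomark`
is for sleep/biomarker researchers who want a tested, reproducible R
implementation of the full measurement-and-modelling chain:

1. **Signal I/O** — EDF reader/writer, plain-TSV hypnograms (30-s epochs over
   W/N1/N2/N3/REM), artifact and respiratory-event annotations.
2. **Preprocessing** — per-kind rate harmonization (polyphase anti-aliased
   resampling), zero-phase 5th-order Butterworth bands (EEG/EOG 0.3–50 Hz,
   EMG 1–90 Hz, airflow 0.1–15 Hz, …), decomposition into per-stage
   concatenated signals (wake discarded), and exclusion of artifact-hit 10-s
   segments.
3. **Features** — in 2-min windows with 50 % overlap, averaged per stage:
   time-domain (RMS, variance, skewness, kurtosis, max), non-linear (Shannon
   entropy, sample entropy SampEn(m = 2, r = 0.2 SD), LZ76 complexity,
   Higuchi fractal dimension), and Welch band powers with median (MF) and
   dominant (DF) frequency — EEG sub-bands δ 0.5–4, θ 4–7, α 8–12,
   spindle 12–14, β 14–30, γ 31–40 Hz. Feature names follow
   `{channel}_{code}_{stage}`, e.g. `EEGO1_A2_sk_N1`.
4. **Sleep parameters** — TST, sleep efficiency, arousal index, AHI (> 15/h
   flags OSA), central/mixed sub-indices, ODI, CT90, SpO2 summaries, stage
   times and latencies.
5. **Selection** — missingness filter (> 50 % dropped), Pearson screen
   against the target (|r| ≥ 0.1 clinical/sleep variables, |r| > 0.3 signal
   features), redundancy pruning at |r| > 0.9, train-statistics z-scoring and
   train-fitted PCA keeping the minimal components for 90 % variance — all on
   the training partition of one shared 75/25 split, leak-free by
   construction.
6. **Models** — a fifteen-model zoo (bagging/extra-trees/random forest,
   gradient boosting with LS/LAD/Huber losses, ridge, lasso, Gaussian
   processes with RBF and Matérn 3/2 kernels and 20 seeded restarts, KNN
   regression, four SVR kernels), tuned by 5-fold CV and scored by train and
   test MAE in pg/ml, aggregated by family.
7. **Synthetic cohorts** — a generator that plants sleep-stage-gated EEG
   content, respiratory events, desaturations and feature–biomarker
   correlations (Gaussian copula) at chosen effect sizes, so the entire
   pipeline is testable end-to-end without patient data.

## A worked example

Generate one synthetic subject-night, derive the clinical sleep report, and
extract quantitative features:

```r
library(somnomark)

spec <- night_spec(duration_min = 20)        # short demo night
gen  <- generate_record(spec, seed = 7, subject_id = "S001")
gen$record
#> <psg_record S001: 9 channels, 20.0 min>

derive_sleep_parameters(gen$record$hypnogram, gen$events,
                        gen$arousals, gen$record$channels$SpO2)
#> TST 18.0 min (SE 90.0%), AHI 26.7/h, ODI 20.0/h, CT90 0.3%

pre <- preprocess_record(gen$record)
pv  <- extract_psgvar(pre, params = nonlinear_params(sampen_decimate = 2))
head(subset(pv, grepl("EEGO1_A2_(sk|alpha|SampEnt)_", feature)), 6)
#>                feature        value n_windows
#> 63      EEGO1_A2_sk_N2  0.032681072         7
#> 67 EEGO1_A2_SampEnt_N2  1.969345563         7
#> 75   EEGO1_A2_alpha_N2  0.080109413         7
#> 83      EEGO1_A2_sk_N3 -0.015055837         3
#> 87 EEGO1_A2_SampEnt_N3  1.026302080         3
#> 95   EEGO1_A2_alpha_N3  0.007958426         3
```

The sleep report reads as a clinician would: 18 of 20 minutes asleep
(efficiency 90 %), 26.7 respiratory events per hour of sleep (above the
15/h OSA threshold), 20 desaturation events per hour, and 0.3 % of sleep
spent below 90 % SpO2 — all of which equal the generator's planted ground
truth exactly. The feature rows are per-stage means over 2-min windows:
N2 sample entropy (≈ 1.97) exceeds N3 (≈ 1.03) because slow-wave sleep is
more regular, and the α-band power is concentrated in N2 rather than N3 —
the planted spectral physiology coming back out of the measurement chain.

A full run — simulate a cohort, select features per biomarker, train the
zoo, write tables, figures and checksums — is one call (or
`exec/somnomark all --out run --seed 17` from a shell):

```r
res <- run_pipeline(run_config(out_dir = "run", seed = 17, n_subjects = 20,
                               mode = "signal", duration_min = 20,
                               sampen_decimate = 2))
family_table(res)   # mean ± SD MAE per model family × subset × biomarker
```

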