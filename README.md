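# bulbarvoice

Acoustic voice biomarkers for detecting and stratifying bulbar impairment
in amyotrophic lateral sclerosis (ALS).

Bulbar ALS changes connected speech early: speaking rate slows, pauses
multiply and lengthen, loudness drops, and the voice source destabilizes
(raised jitter and shimmer, reduced harmonics-to-noise ratio).
`bulbarvoice` implements an automated analysis of passage-reading
recordings for researchers working on speech-based ALS monitoring:

1. **Preprocessing & QC** — spectral-subtraction noise reduction (0.025 s
   Hann windows, 80 Hz–10 kHz suppression range, 40 Hz smoothing, ≥ 0.25 s
   noise sample) and quality gates (SNR > 30 dB, clipping < 1% of
   samples).
2. **Feature extraction** — a 53-feature acoustic set fixed by a versioned
   manifest: jitter (5), shimmer (6), harmonicity (5), fundamental
   frequency (7), intensity (7), zero-crossing rate (2), and timing/rate
   (21) features covering the phonatory, respiratory and articulatory
   speech subsystems.
3. **Classification** — Bayesian LASSO logistic regression,

   y_i ~ Bernoulli(σ(α + x_i'β)),  α ~ N(0, 1),  β_k ~ Laplace(0, 0.5),

   fitted by a Pólya–Gamma Gibbs sampler, evaluated over ten stratified
   pseudorandom 50/50 train/test splits with AUROC aggregation
   (mean ± SD) and median-across-folds coefficient summaries. Class 1 is
   the less-impaired group, so positive coefficients mean the
   less-impaired group scores higher.
4. **Sex-interaction testing** — sex × feature interaction variants for
   the F0/HNR subsets, compared to the no-interaction model by WAIC with
   a 2-standard-error substantiality rule.
5. **Synthetic data** — vowel-like audio with controllable F0, jitter,
   shimmer, noise, clipping and pause schedules, plus feature-level
   cohorts (default: 119 ALS / 22 controls, FRS-bulbar median 11, IQR 3)
   with configurable standardized effect sizes — so the whole pipeline is
   testable without access-restricted clinical recordings.

Subjects are stratified by the FRS-bulbar score (0–12): ≥ 11 is early
(ALS-E), < 11 late (ALS-L); three binary contrasts are run (control vs
all ALS, control vs ALS-E, ALS-E vs ALS-L).

## Worked example

```r
library(bulbarvoice)
# cohort emulating the study: 119 ALS / 22 controls, realistic effect sizes
cohort <- generate_cohort(cohort_config(effect_map = as.list(als_effect_map()),
                                        seed = 1))
cohort <- stratify_cohort(cohort)
res <- run_binary_comparison(cohort, "control_vs_als",
                             model_config(seed = 1), n_reps = 10)
print(res)
#> <comparison_result> control_vs_als (n = 141): AUROC 0.993 +/- 0.006 over 10 folds
#>   top |median coefficients|: speech_rate=1.03, articulation_rate=0.91,
#>   pause_time=-0.65, n_pauses=-0.61, word_dur_mean=-0.50
```

The cohort was generated with slowed rate, longer pausing and reduced
loudness in the ALS group; the classifier separates the groups almost
perfectly at these effect sizes (mean test AUROC 0.993 over the ten
held-out halves) and the aggregated coefficients recover the planted
directions: positive weights on speech and articulation rate (higher in
controls), negative on pause time, pause count and word-unit duration
(higher in ALS).

Audio-level use follows the same surface:

```r
rec  <- read_wav("subject01.wav")            # mono PCM WAV
prof <- estimate_noise_profile(rec)          # first 0.25 s = noise lead-in
den  <- spectral_subtract(rec, prof)
qc   <- qc_gate(den)                         # SNR > 30 dB, clipping < 1%
fv   <- extract_features(den)                # named 53-vector
```

`run_pipeline()` / `export_report()` orchestrate the whole flow (audio
directory or feature CSV in; `features.csv`, per-fold ROC points,
`coefficients.csv`, `qc.jsonl`, `report.json` out), and
`inst/cli/bulbarvoice-cli.R` wraps them for shell use:

```sh
Rscript inst/cli/bulbarvoice-cli.R simulate --out cohort.csv --seed 1
Rscript inst/cli/bulbarvoice-cli.R run-all --features cohort.csv --out results/
```

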