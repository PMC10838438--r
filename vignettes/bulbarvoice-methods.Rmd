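---
title: "Acoustic voice biomarkers for bulbar ALS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic voice biomarkers for bulbar ALS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bulbarvoice)
```

## The problem

Bulbar involvement in amyotrophic lateral sclerosis (ALS) degrades the
respiratory, phonatory and articulatory subsystems of speech well before it
is florid clinically: speaking rate falls, pauses lengthen and multiply,
loudness drops, and the voice source becomes unstable (raised jitter,
shimmer, lowered harmonics-to-noise ratio). `bulbarvoice` implements an
automatic pipeline that turns a passage-reading recording into a 53-feature
acoustic profile and classifies bulbar status with a sparse Bayesian
logistic model. Three binary contrasts are supported: control vs all ALS,
control vs early-bulbar ALS (ALS-E), and ALS-E vs late-bulbar ALS (ALS-L),
where severity strata come from the revised ALS Functional Rating Scale
bulbar subscale (FRS-bulbar, 0--12, higher = less impaired): scores
$\geq 11$ are ALS-E, scores $< 11$ ALS-L; subjects with missing scores take
part only in the control-vs-all-ALS contrast.

Clinical voice recordings of this kind are access-restricted, so the
package carries a first-class synthetic-data module that generates both
vowel-like audio with known ground truth and feature-level cohorts with
configurable effect sizes. Every downstream stage is tested against those
known truths.

## Noise reduction and quality control

Recordings are denoised by short-time spectral subtraction in the Boll
dialect: Hann analysis windows of 0.025 s with 50% overlap, the noise
magnitude spectrum estimated as the mean magnitude over a noise-only
segment of at least 0.25 s (by default the first 0.25 s of the recording,
which therefore must be a silent/noise lead-in), smoothed by a moving
average of 40 Hz bandwidth, scaled by an oversubtraction factor of 2 and
subtracted from each frame's magnitude within the 80 Hz--10 kHz
suppression range only. A spectral floor at 2% of the noise magnitude
prevents negative magnitudes; the noisy phase is reused and frames are
overlap-added back, so output length always equals input length. The
window length, band, smoothing bandwidth and minimum noise-sample duration
are the method's published settings; the 50% overlap, floor and
oversubtraction factor are not published for the reference tool and follow
common practice for the algorithm.

One consequence worth knowing: the suppression band is a property of the
algorithm, so broadband noise *above* 10 kHz is deliberately untouched. In
tests that measure noise-reduction gain we therefore sample fixtures at
20 kHz, where the band spans the full bandwidth; at 44.1 kHz more than
half of a white noise floor lies out of band and caps the measurable gain
near 3 dB regardless of implementation quality.

Quality control applies two gates: estimated SNR strictly greater than
30 dB and clipped samples (|x| at or above 99.9% of full scale) strictly
below 1% of samples — the boundary values fail. The SNR estimator is
energy-based: 10 ms frames, frames within 25 dB of the 95th-percentile
frame level count as speech-active, the rest as silent, and SNR is
$10\log_{10}$ of the active/silent mean-power ratio capped at +60 dB. When
the relative threshold yields no silent frames (e.g. unbroken stationary
noise, or moderate-SNR material whose noise floor sits within 25 dB of
speech) a two-means split of the frame levels is tried and trusted only if
the two modes separate by more than 6 dB; otherwise the SNR is reported
indeterminate, which fails the gate with its own reason. Whether the
reference analysis gated on pre- or post-reduction SNR is unstated; the
pipeline gates on the post-reduction signal and records both values.

## The 53-feature acoustic set

The exact feature composition is fixed by a versioned JSON manifest
(`inst/extdata/feature_manifest.json`), swappable without code changes:
5 jitter + 6 shimmer + 5 harmonicity + 7 F0 + 7 intensity + 2
zero-crossing + 21 timing/rate features = 53. The reference feature list
is proprietary; this manifest reconstructs it from the published category
inventory and abbreviations.

* **Pitch** is tracked by normalized autocorrelation on 40 ms frames at a
  10 ms hop, searching 75--500 Hz, with parabolic refinement of both the
  lag and the peak value, a small octave cost ($0.01$ per octave) and a
  subharmonic correction that prefers lag $L/2$ whenever its correlation
  reaches 75% of the best peak — without the correction, injected jitter
  produces isolated octave-down frames that masquerade as skipped cycles.
  A frame is voiced when the refined peak reaches $r \geq 0.45$.
* **Pulses** (glottal cycle marks) are placed at peaks of the smoothed
  amplitude envelope (analytic-signal magnitude, low-passed at
  $\min(600, 1.4 f_0)$ Hz — above the f0 modulation rate, below the first
  formant), walking outward from the strongest peak by the locally
  predicted period and refining each mark by parabolic interpolation to
  sub-sample precision. Per-cycle amplitudes are parabolic-refined
  waveform peak magnitudes. Sub-sample precision matters: at 44.1 kHz a
  half-sample quantization error is itself ~0.2% "jitter" at 150 Hz,
  larger than the 0.1% floor the extractor achieves.
* **Jitter/shimmer** follow the perturbation-quotient definitions
  (local, absolute, RAP, PPQ5, DDP; local, local-dB, APQ3/5/11, DDA),
  with the algebraic identities DDP = 3 RAP and DDA = 3 APQ3 holding to
  machine precision. Minimum cycle counts (3, 5, or 11 by measure) are
  enforced; short or unvoiced material yields missing values.
* **Harmonicity** converts the per-frame autocorrelation peak $r$ to
  HNR $= 10\log_{10}(r/(1-r))$, capped at $\pm 60$ dB; `ac_mean` is the
  mean $r$, `cc_mean` the mean Pearson correlation of successive cycles,
  and the noise-to-harmonics ratio averages $(1-r)/r$.
* **Intensity** statistics are dB-re-full-scale frame RMS levels over
  speech-active frames; because the activity threshold is relative,
  rescaling the waveform by $c$ shifts every intensity feature by exactly
  $20\log_{10} c$ and changes nothing else.
* **Segmentation** marks sub-threshold runs of at least 0.15 s as pauses
  (shorter dips are absorbed into speech) and classes them as short
  (0.15--0.5 s), medium (0.5--1.0 s) or long (> 1.0 s); the class
  boundaries are this package's choice, as the reference publishes the
  classes but not their cutoffs. Syllable nuclei are intensity peaks of at
  least 2 dB prominence within speech segments; speech rate divides the
  nucleus count by total duration, articulation rate by speech time only.
* **Word-unit durations** are speech-chunk durations standing in for
  words: the reference pipeline used transcript alignment that cannot be
  replicated without transcripts. This is a documented deviation.

## The synthetic-data generator

**Audio level.** The voice source is a glottal pulse train exciting a
two-formant resonator (~700/1200 Hz, bandwidths 90/120 Hz), giving
speech-like spectra that exercise the pitch tracker and HNR machinery more
realistically than a sawtooth. Jitter and shimmer are injected as i.i.d.
Gaussian per-cycle perturbations truncated at $\pm 3\sigma$ — matching the
perturbation-quotient definitions under test. Pulses are rendered as
narrow Gaussians at real-valued centres so that the synthesized period is
exact to sub-sample precision. Pauses are inserted as digital silences at
scheduled positions; optional white noise is scaled to a target SNR and
the components kept for direct power measurement. Synthesis is
deterministic per seed. Perturbation-recovery baselines hold to < 0.1%
for fundamental frequencies up to ~220 Hz; at 300 Hz the resonator decay
overlaps adjacent cycles and the shimmer baseline degrades to ~0.4%, so
periodic-fixture perturbation checks use the 100--220 Hz speaking range
while F0-accuracy checks span 100--300 Hz.

**Feature level.** Cohort tables are drawn from a multivariate normal
with unit variances, correlation $\rho = 0.5$ within each manifest
category and zero across categories — rate and pause features plausibly
measure the same constructs, and block correlation stresses the
classifier's handling of collinearity. Group effects are standardized mean
differences with the sign convention *positive = less-impaired group
higher*; less-severe ALS rows (FRS $\geq 11$) receive 0.8 of the
configured shift, more-severe rows 1.2, so all three contrasts are
separable in proportion to the configured effects while the overall
control--ALS difference matches the map. The default cohort mirrors the
study composition: 119 ALS (47 female) vs 22 controls (12 female),
FRS-bulbar integers matched to median 11 / IQR 3 via a rounded normal,
and 26/119 ALS rows with missing FRS. `als_effect_map()` supplies a
realistic effect pattern (slowed rate, more pausing, reduced loudness and
F0 range, raised perturbation; $|d| \leq 1.5$).

What the generator does *not* emulate: consonant articulation, words and
phrase structure, longitudinal progression, non-normal feature marginals,
and cross-category correlations. Passing tests demonstrate that the
pipeline recovers what the generator encodes — they do not certify
performance on clinical recordings.

## The classifier

The model is logistic regression with a global intercept
$\alpha \sim N(0, 1)$ and per-feature coefficients
$\beta_k \sim \mathrm{Laplace}(0, 0.5)$ (scale parameter $b = 0.5$),
$k = 1 \ldots 53$, and a Bernoulli likelihood through the logistic link.
The Laplace prior is the Bayesian LASSO: it compresses weak coefficients
towards zero while letting strong ones persist, and the package exposes a
Normal$(0,1)$ prior variant so the shrinkage difference can be
demonstrated on identical data. There is no hyperparameter tuning.

Sampling uses a Gibbs sampler with Pólya-Gamma data augmentation, with the
Laplace prior handled through its exponential scale-mixture
representation, so every conditional update is exact and conjugate. A
gradient-based sampler would fit the same posterior; the conjugate scheme
was chosen because it is an established dialect for exactly this model,
has no step-size tuning to fail, and at these problem sizes runs an order
of magnitude faster — which the repeated-split protocol (30+ fits per
analysis) rewards. Defaults are 4 chains of 1000 warmup + 1000 retained
draws. Convergence is gated on the split-chain R-hat of every parameter at
1.01; a failing fit is retried once with doubled iterations and flagged if
still failing (flagged folds are excluded from AUROC aggregation and
reported). The per-draw pointwise log-likelihood matrix is stored for
WAIC.

**Evaluation protocol.** Each contrast is evaluated over ten pseudorandom
class-stratified 50/50 train/test partitions (the reference describes
repeated 50/50 splits while calling them "tenfold cross-validation"; the
explicit description wins). Per fold: missing features are imputed with
training-half medians, columns are standardized by training mean and SD
(zero-variance training columns dropped and logged), the model is fitted
on the training half only, and the held-out half is scored by the
posterior-mean inverse-logit. AUROC uses the Mann-Whitney mid-rank
formulation (ties count one half; a single-class fold is flagged, not
crashed). Test rows never touch the imputation medians, the scaler or the
posterior, and the per-fold audit records kept in every result make that
checkable after the fact. Class 1 is always the less-impaired group
(control, control, ALS-E), so positive coefficients mean the
less-impaired group scores higher — the published sign convention.
Per-fold posterior-median coefficients are aggregated across folds by the
median.

## Sex-interaction comparison by WAIC

Sex enters the design as a 0/1 main effect (female = 0) in both models;
the interaction variant additionally appends elementwise
sex-times-feature products for the F0 features and the two HNR summaries
— the subsets where vocal physiology differs most by sex. Interaction
coefficients get the same Laplace prior. Models are compared per training
fold by WAIC $= -2(\mathrm{lppd} - p_{\mathrm{waic}})$ with
$p_{\mathrm{waic}}$ the summed pointwise posterior variances of the
log-likelihood. "Substantially better" is quantified as the WAIC
difference exceeding twice the standard error of its pointwise terms — a
standard rule; the reference states the criterion only qualitatively.
Ties and sub-threshold differences retain the simpler model, the decision
is antisymmetric in model order, and the overall verdict is the majority
across folds. The fold-level comparison (rather than a single full-data
fit) mirrors the protocol's "ten trained models" framing and exposes the
decision's stability.

## Numerical choices and degenerate inputs

* SNR and HNR are capped at $\pm 60$ dB; autocorrelations are clamped to
  $(10^{-6}, 1 - 10^{-6})$ before the log-ratio.
* All-silent input: no voiced frames, no speech segments, phonatory and
  intensity features missing, timing features defined (whole duration one
  pause).
* Fewer than 3 pulses: the pulse sequence is missing-marked and all
  perturbation features propagate as missing with per-feature flags.
* A training column with zero variance is dropped from both halves and
  recorded in the scaler; an all-missing training column imputes to 0
  after which the zero-variance rule removes it.
* Master-seed fan-out: every stage derives its own seed by a stable hash
  of the stage label, so identical configuration and seed reproduce every
  split, fit and report bit-for-bit while stages stay independent.

## Problem sizes in the test suite

The suite exercises the full study geometry where the property being
checked depends on it (141-row cohorts, ten 50/50 splits, 53 features;
parameter-recovery at $n = 200$ with 5 true coefficients of $|\beta| = 1$;
ten-seed ladders for shrinkage and sign-recovery claims) and reduced
sampler settings (2 chains, 300-500 draws) where only structure is under
test. Audio integration tests use 16--20 kHz fixtures of 1--2 s.

## Known limitations

* The manifest is a reconstruction; the proprietary feature list it
  stands in for may differ in composition and definitions.
* Word-unit timing uses speech chunks, not transcript-aligned words.
* The generator's normal, block-correlated feature model and its
  severity weighting (0.8/1.2) are modelling choices, not estimates from
  data; no distributional description of the real features is published.
* High-pitched voices (~300 Hz) show inflated shimmer baselines from
  cycle overlap in the resonator output.
* The pipeline performs no visual spectrogram inspection and no
  narrowband-noise classification; the corresponding manual screening
  step of the reference workflow has no automated counterpart here.
* No multiclass (three-way) model, no age/education covariates, no
  mel-frequency cepstral coefficients.
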