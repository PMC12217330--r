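---
title: "Measuring acute levodopa effects on speech: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acute levodopa effects on speech: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levospeech)
```

## The problem

More than 90% of people with Parkinson's disease develop hypokinetic
dysarthria: monopitch, monoloudness, imprecise consonants, timing
abnormalities, and a harsh or breathy voice. Whether an acute dose of
levodopa changes speech has been hard to establish by ear, because the
treatment-related changes are subtle and spread across several speech
domains. Digital speech biomarkers — scalar acoustic quantities computed
from a short, standardized recording protocol — can measure those domains
with far more sensitivity than perceptual rating.

`levospeech` implements the full analysis chain for a paired OFF/ON
medication design: 16 biomarkers extracted from three tasks (sustained /a/
phonation, fast /pa/-/ta/-/ka/ repetition, and passage reading), paired
statistics, data-driven models of which biomarker changes track hypokinetic
and hyperkinetic (dyskinetic) symptom change, weighted compound speech
scores, and a classifier for the direction of a medication-state
transition. Because recordings of patients cannot be shared, the package
also contains a ground-truthed synthetic generator for both audio and
feature-level cohorts; every stage is tested against planted truth.

## The 16 biomarkers

From the reading task: `sdF0_text` (semitone sd of F0; monopitch),
`Int_sd_text`, `Int_kurt_text`, `Int_skew_text` (dB intensity distribution;
monoloudness), `NSR_text` (net speech rate, syllables per second of net
speech time), `DPI_text` (mean pause duration, ms), `RST_text` (rate of
speech timing), and the four long-term average spectrum (LTAS) moments
(`LTAS_mean`, `LTAS_sd`, `LTAS_skew`, `LTAS_kurt`), treating the Welch
power spectrum over 0–8 kHz as a distribution over frequency. From
phonation: `MPT_phon` (maximal phonation time), `HNR_phon`
(harmonics-to-noise ratio), `Int_slope_phon` (dB/s intensity trend;
respiratory control), `Int_sd_phon`. From syllable repetition: `VOT_ddk`
(voice onset time, burst onset to voicing onset).

### Acoustic analysis choices

The literature this protocol comes from defers algorithmic detail to prior
methodological work, so the package fixes and documents its own defaults:

* **Framing**: 40 ms frames, 10 ms hop. **F0 range**: 60–400 Hz.
* **Pitch**: window-corrected autocorrelation, voicing threshold 0.45, with
  parabolic peak interpolation, a small octave cost (0.04 per octave of
  lag) and sub/super-harmonic rejection at half an octave from the voiced
  median. Pitch analysis runs on a 12 kHz decimated copy; harmonicity (HNR)
  is computed at the native rate so the full noise band counts, as
  `10*log10(r/(1-r))` from the autocorrelation peak `r`.
* **sdF0** is computed in semitones, which makes it independent of the
  speaker's register.
* **Segmentation**: energy threshold 25 dB below the track maximum, with
  minimum pause and minimum speech segment durations of 60 ms (standard
  dysarthria-segmentation floors, configurable), half-hop boundary
  correction, and pause-boundary refinement on a 1 ms envelope. `DPI` is
  the mean pause duration; `RST` is the count of speech plus pause segments
  per minute of passage duration — the field uses several variants of this
  quantity, and this definition is a documented stand-in chosen to be
  monotone in speech/pause alternation rate.
* **Intensity statistics** use speech frames for the reading task and
  voiced frames within the phonation stretch (trimmed 50 ms at each end);
  the distinction matters because reading intentionally contains pauses.
* **LTAS** uses linear power weights over 0–8 kHz (a dB-weighting dialect
  is available via `db_weight`), and the moments use the Pearson
  convention (normal kurtosis = 3).
* Missing features are explicit `NA` markers, never silent zeros.

All intensity-derived features live on the dB contour, so every biomarker
is invariant to a constant amplitude rescaling of the recording; the test
suite asserts this, along with time-reversal invariance of the
distributional features.

## The synthetic generator

### Audio

The glottal source is a sum of 10 harmonics with a −12 dB/octave rolloff —
deliberately simple so every planted parameter is analytically recoverable:
vibrato of amplitude `f0_sd * sqrt(2)` gives an F0-track sd of exactly
`f0_sd` semitones; additive white noise at `snr` dB gives an expected HNR
equal to the SNR; a linear dB/s envelope gives the intensity slope; DDK
syllables are burst + high-passed aspiration + vowel with the voice onset
time planted directly. Formant filtering is intentionally absent (it would
make the LTAS moments depend on an arbitrary vocal-tract model). What the
audio generator does *not* emulate: real phonetics, intelligibility,
language content, room acoustics, or microphone variation — so passing
recovery tests demonstrates correctness of the extraction algorithms, not
robustness to in-the-wild recordings.

### Cohorts

The feature-level generator emulates a cohort of `n_pd = 51` patients with
motor fluctuations and `n_hc = 43` controls. Each patient has a latent
dopaminergic response `D ~ N(1, 0.3)` truncated at zero. Planted feature
changes are `eta_k = a_k * effect_scale * D + N(0, noise_sd)` in latent
units (loading signs set the direction), scaled to natural units by 0.2 HC
sd per latent unit. The hypokinetic outcome (MDS-UPDRS-III without tremor
items, bounded by its 92-point no-tremor maximum) loads *negatively* on the
realized planted changes plus a feature-independent improvement intercept;
the hyperkinetic outcome (Marconi axial subscore, 0–12) loads positively on
its six planted changes. Having the outcomes load on the realized
per-feature changes — rather than on `D` alone — is a deliberate design
choice: with a single scalar mediator the planted features would be
mutually redundant proxies and no selection procedure could be expected to
retain most of them; the realized-change formulation gives each biomarker
its own pathway into the outcome, which is also the structure the
regression models assume.

Clinical scores are integerized at MDS-UPDRS item level (laterality
collapsed, item caps respected, no-tremor maximum 92), with the no-tremor
change split 50/35/15 across bradykinesia/axial/rigidity subscores and an
independent tremor change — so subscore prediction has real structure to
find. OFF severity is drawn correlated with the response magnitude
(stronger responders start higher), which is both clinically natural and
keeps ON-state scores off the scale floor.

**Calibration.** Default noise values (`noise_sd = 2.5` latent units,
outcome noise 7.2 points, gain 1, intercept −12) were fixed from the
closed-form design target — final-model in-sample R² near 0.6 with
per-feature AIC-retention noncentrality ≈ 6 — and then confirmed once by
simulation: across 50 seeds the backward-stepwise hypokinetic model
recovers ≥ 6 of the 8 planted features in ~88% of seeds, median in-sample
R² ≈ 0.66, median compound-score correlation ≈ 0.77, and median transition
LOOCV AUC ≈ 0.88. The `effect_scale = 0` null switch removes all planted
structure.

## Statistics

* Paired OFF/ON comparisons route on the Shapiro–Wilk normality of the
  *paired differences* (they are what the tests see) at α = 0.05: paired t
  with Cohen's d, or Wilcoxon signed-rank with the matched-pairs
  rank-biserial correlation `(W⁺ − W⁻)/(W⁺ + W⁻)`. Holm–Bonferroni
  adjustment across the 16-biomarker family.
* Change direction is ON − OFF throughout; improvement on the motor scale
  is therefore negative.
* PD-vs-HC contrasts adjust for age, gender (binary indicator), and MoCA;
  language is not a covariate.
* The power of the paired design uses the exact noncentral-t formula; at
  n = 51, α = 0.05 two-sided it gives 0.94 for d = 0.5 and 0.998 for
  d = 0.7, verified against a 100,000-replicate Monte Carlo.

## Models, importance, compound scores

Both symptom models start from all 16 change scores (backward stepwise by
AIC, `k = 2`; removal ties broken by lexicographic candidate order).
Relative importance uses proportional marginal variance decomposition
(pmvd): an ordering-average of sequential R² increments with weights
proportional to `prod_i 1/(R²_full − R²(first i))`, computed exactly via a
dynamic program over the memoized 2^p subset-R² lattice (p ≤ 12; a seeded
ordering-sampling mode exists above that). LMG (equal ordering weights) is
implemented as the cross-check oracle; degenerate zero gaps in the pmvd
weights are regularized at 1e−12. pmvd's defining behavior — a
zero-coefficient correlated predictor receives a vanishing share — is
asserted in the tests.

The compound scores z-score each selected change against the PD cohort's
change distribution (the reference is captured in the score definition, so
the choice is explicit and portable), weight by normalized pmvd shares, and
apply the sign of the regression coefficient. The definition is invariant
to affine rescaling of any raw feature.

## Evaluation

LOOCV holds the selected feature set fixed and refits coefficients per fold
(this mirrors the usual practice of selecting once on the full sample; a
`nested_selection` flag re-runs selection inside each fold for an honest
optimism estimate). `R²_pred = 1 − SSE_loo/SST` may be negative.

The medication-state-transition experiment assigns each subject a fair-coin
label: 0 keeps the ON−OFF change vector, 1 negates it. The published
description of the class-0 construction mentions an "absolute difference",
which read literally would discard sign information and make the two
classes indistinguishable; the signed orientation implemented here is the
only construction consistent with simulating transition directions.
Stepwise logistic selection runs on the union of the hypokinetic and
hyperkinetic selections; AUC comes from pooled LOO probabilities, the
confusion metrics from a 0.5 threshold, and the accuracy CI is
Clopper–Pearson.

**Null behavior worth knowing about.** On a cohort with no planted effect,
backward selection still fits noise, so the *in-sample* compound
correlation and the non-nested LOOCV AUC are optimistically biased (a
well-known property of selection-then-evaluate workflows, not a defect of
the implementation). The package's null checks therefore use the honest
constructions: the compound score against a permuted outcome (median |r| ≈
0.11 at n = 51), and nested-selection LOOCV for the transition AUC (median
≈ 0.53 on null cohorts).

## Problem sizes

The test suite and the acceptance script run the full chain at the study's
own scale (n = 51 + 43): 50 simulated cohorts for the calibration
properties in the tests (40 in the acceptance script), 9–11 nested-LOOCV
null cohorts, 20 seeds for audio parameter recovery, and a 100,000-rep
power Monte Carlo — sizes chosen so the whole suite completes comfortably
on a single CPU while keeping the binomial noise of the seed-level
fractions small.

## Limitations

The synthetic cohort is a single-factor response model with independent
feature noise given the response; real biomarker changes are likely
inter-correlated beyond their shared response (the generator exposes the
noise structure per feature but defaults to conditional independence).
Effect sizes, noise levels, and HC reference ranges are field-plausible
choices, not estimates from any dataset; conclusions about real patients
require real recordings. The acoustic front end is deliberately tuned for
the clean, close-microphone protocol — it is not a noise-robust
in-the-wild pipeline, and amplitude-dependent features remain sensitive to
recording conditions in general.
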