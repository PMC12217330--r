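# levospeech

Digital speech biomarkers of acute levodopa response in Parkinson's disease.

Hypokinetic dysarthria — monopitch, monoloudness, imprecise consonants,
timing abnormalities, dysphonia — affects most people with Parkinson's
disease, and acute medication effects on speech are too subtle to judge
reliably by ear. `levospeech` implements a complete digital-biomarker
analysis chain for a paired OFF/ON medication design, for clinical speech
researchers and methodologists:

* **Acoustics** — 16 biomarkers from three standard tasks: sustained /a/
  phonation (`MPT`, `HNR`, intensity slope/sd), /pa/-/ta/-/ka/ repetition
  (`VOT`), and passage reading (`sdF0`, intensity sd/kurtosis/skewness,
  `NSR`, `DPI`, `RST`, and the four long-term-average-spectrum moments).
* **Statistics** — Shapiro-routed paired t / Wilcoxon comparisons with
  Holm–Bonferroni correction and effect sizes; age/gender/MoCA-adjusted
  contrasts against healthy controls; test–retest reliability; exact
  noncentral-t power for the paired design.
* **Modeling** — backward stepwise AIC regression of hypokinetic
  (MDS-UPDRS-III without tremor items, /92) and hyperkinetic (Marconi
  axial dyskinesia subscore, /12) symptom change; proportional marginal
  variance decomposition (pmvd) relative importance; weighted z-scored
  compound speech scores `sum_k sign(b_k) w_k z_k`.
* **Evaluation** — leave-one-out cross-validation (MAE, RMSE, predictive
  R²), per-subscore prediction, and a randomized medication-state-transition
  classifier (stepwise logistic + LOOCV ROC/AUC).
* **Synthesis** — ground-truthed audio (harmonic source, planted F0
  contour, SNR, timing) and feature-level OFF/ON cohorts with a latent
  dopaminergic-response structure, so the whole chain is testable without
  patient data.

## Worked example

```r
library(levospeech)

# a synthetic study at the design's scale: 51 PD pairs, 43 controls
cohort <- gen_cohort(synthetic_cohort_spec(seed = 1))
res    <- analyze_cohort(cohort, seed = 1)
res
#> <levo_analysis>
#> == hypokinetic model ==
#> <stepwise_result> linear; 8 selected of 16 candidates; AIC 196.52
#>   R2 0.687  adj R2 0.627
#>    (Intercept)  Int_kurt_text Int_slope_phon      LTAS_kurt      LTAS_mean
#>      -13.02131        6.26649        6.18991       -1.11748        0.08180
#>      LTAS_skew       NSR_text       RST_text        VOT_ddk
#>       10.42459       13.79015       -0.75434       -1.14640
#>   compound r = 0.803
#> <evaluation_report> LOOCV regression: MAE 5.513  RMSE 7.032  R2_pred 0.533
#> == hyperkinetic model ==
#> <stepwise_result> linear; 6 selected of 16 candidates; AIC 94.27
#>   R2 0.381  adj R2 0.297
#> ...
#> == transition model ==
#> <evaluation_report> classification: AUC 0.824  acc 76.5% (CI 0.63-0.87)
#>   sens 0.81  spec 0.71  ppv 0.76  npv 0.77;  7 features
```

The hypokinetic model keeps eight of the sixteen candidate biomarker
changes (seven of them are planted responders in this cohort) and explains
69% of the variance in the motor-score change in sample; the compound
speech score correlates r = 0.80 with the clinical change and predicts it
with a LOOCV error of ~5.5 points on the 92-point no-tremor scale;
randomly assigned medication-state transitions are recognized from the
oriented biomarker changes with AUC 0.82. Exact numbers vary with the
seed; what the test suite checks are the calibrated multi-seed properties
and the planted generator truth.

Audio works the same way end to end:

```r
truth <- audio_ground_truth("phon", phonation_dur = 3, intensity_slope = -2,
                            snr = 20, seed = 4)
round(phonation_features(synth_phonation(truth))[c("MPT_phon", "HNR_phon", "Int_slope_phon")], 3)
#>       MPT_phon       HNR_phon Int_slope_phon
#>          2.997         19.808         -1.994
```

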