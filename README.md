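# restpower

Resting-state EEG band power, asymmetry and diagnostic modelling for
two-group (patient vs. control) studies of major depressive disorder (MDD).

Clinical resting-state EEG studies of depression typically compare relative
spectral band power between patients and controls across scalp regions and
hemispheres, then combine the discriminating features into a logistic
diagnostic model. `restpower` implements that complete workflow as a tested,
reusable R package:

- **Preprocessing** of 19-channel 10–20 recordings: zero-phase 1–40 Hz
  band-pass and 49–51 Hz notch (windowed-sinc FIR), downsampling, FastICA
  ocular-artifact removal, 2-s epoching, ±150 μV amplitude rejection, and
  average re-referencing — in that fixed, provenance-logged order.
- **Spectral features**: per-epoch Hann periodograms; absolute and relative
  power in six bands — delta [1,4), theta [4,8), alpha [8,12), beta1
  [12,16), beta2 [16,24), beta3 [24,40] Hz — for ten regions of interest
  (PFC, RMFC, LMFC, CC, PP, LT, RT, MOC, RMOC, LMOC), plus right-minus-left
  asymmetry scores for the three homologous ROI pairs. Relative powers
  always sum to one per ROI.
- **Group statistics**: Welch/pooled t contrasts with Benjamini–Hochberg FDR
  per (eye state × feature family), Cohen's d (control-minus-patient
  convention), chi-square demographics, and Pearson correlations of features
  with symptom severity (HDRS-17).
- **Diagnostic model**: unpenalized logistic regression on selected
  features, stratified 10-fold cross-validated AUC/sensitivity/specificity
  (fold cut-offs from training-set Youden indices), percentile-bootstrap 95%
  AUC confidence interval, and per-feature ROC with Youden-optimal cut-offs.
- **Synthetic cohorts**: a deterministic generator producing two-group EEG
  cohorts (1/f background + band-limited oscillations, eye-state alpha
  reactivity, configurable regional group effects and hemispheric asymmetry
  shifts, blink/excursion artifacts with ground truth, severity scores
  coupled to frontal beta2 amplitude), so the whole pipeline is testable
  without access to clinical data.

The central quantity is relative band power
`RP(roi, b) = P(roi, b) / Σ_b' P(roi, b')` with `P` the PSD integral over
band `b`, and the asymmetry score `A(pair, b) = RP(right, b) − RP(left, b)`.
The diagnostic model is `logit P(MDD) = β₀ + Σ_j β_j x_j` over a declarative
feature list (defaulting to the eyes-open frontal/central beta2 and
occipital beta3 powers, the eyes-closed regional powers, and the temporal
asymmetries).

## Worked example

Simulate a desk-scale study (40 subjects per group, 60 s per eye state at
250 Hz) and run the full pipeline:

```r
library(restpower)

spec <- simulation_spec(seed = 11)
res <- run_study(
  spec,
  config = preprocess_config(resample_hz = NULL, ica = FALSE),
  artifacts = FALSE, seed = 11
)

res$model
#> <model_report> 18 features | CV AUC 0.8938 (95% CI 0.7769-0.9356) | sens 0.800 spec 0.775 (Youden)

pw <- subset(res$stats, feature_type == "power")
head(pw[order(pw$p_fdr), c("eye_state", "region", "band", "p_raw", "p_fdr", "cohen_d")], 3)
#>   eye_state region  band        p_raw      p_fdr    cohen_d
#>          EO   LMFC beta2 0.0002135744 0.01281446 -0.8707119
#>          EO    PFC beta2 0.0007566386 0.02269916 -0.7842868
#>          EO   RMFC beta2 0.0018797562 0.03759512 -0.7201663
```

The smallest FDR-adjusted p values among power features are the eyes-open
frontal beta2 elevations in the patient group (negative d = patient mean
larger), the pattern the generator's defaults encode; the cross-validated
AUC near 0.89 is the model's discrimination under 10-fold CV for this
cohort. `res$correlations` holds the feature–severity correlations
(eyes-open PFC beta2 vs HDRS-17 is calibrated to a cohort-mean r ≈ 0.2),
`res$features` the tidy per-subject feature table,
and `res$retention` per-recording epoch counts. With `out_dir =` the tables,
model report and a config-hashed run log are written to disk; recordings
round-trip through EDF (`write_edf()`/`read_edf()`) or a flat binary matrix
with JSON sidecar.

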