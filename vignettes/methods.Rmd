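---
title: "Methods: resting-state EEG band power, asymmetry and diagnostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state EEG band power, asymmetry and diagnostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(restpower)
```

`restpower` implements a complete resting-state EEG biomarker workflow for
two-group (patient vs. control) studies of major depressive disorder:
preprocessing of multichannel 10–20 recordings, six-band relative spectral
power over ten regions of interest (ROIs), right-minus-left hemispheric
asymmetry scores, FDR-corrected group contrasts, and a cross-validated
logistic diagnostic model with ROC/Youden analysis. Because raw clinical EEG
cohorts of this kind are rarely shareable, the package also contains a
first-class synthetic cohort generator that emulates the statistical
structure of such a study, making every downstream stage testable end to
end.

## The analysis model

Each subject contributes one eyes-open (EO) and one eyes-closed (EC)
resting-state recording from 19 Ag/AgCl electrodes in the international
10–20 layout. After preprocessing, each retained 2-s epoch yields a
one-sided Hann-tapered periodogram per channel (0.5 Hz resolution, scaled so
that the PSD integrates to the tapered signal's variance). Absolute band
powers are PSD integrals over six bands — delta [1,4), theta [4,8), alpha
[8,12), beta1 [12,16), beta2 [16,24), beta3 [24,40] Hz — with half-open
edges so shared boundaries are counted once and the six relative powers
(band power divided by total 1–40 Hz power) sum exactly to one. A secondary
band-power estimator (zero-phase Butterworth band-pass followed by the
analytic-signal mean instantaneous power) is provided and tested to agree
with PSD integration within 10% on band-limited signals; the two estimators
are the classical alternatives and their mutual agreement is part of the
package's contract.

Channel-level relative powers are averaged across retained epochs *on the
relative scale* (not the absolute scale). This choice matters only when the
total power varies strongly across epochs; averaging fractions weights every
epoch equally, which is the reading most consistent with per-epoch
normalization, and is fixed here for determinism.

The ten ROIs (PFC, RMFC, LMFC, CC, PP, LT, RT, MOC, RMOC, LMOC) each pool
three electrodes; the midline electrodes Fz and Pz are shared between
overlapping ROIs. ROI relative power is the unweighted mean of the
channel-level relative-power vectors, renormalized to sum to one (a no-op up
to rounding, since a mean of sum-to-one vectors sums to one). Asymmetry
scores are raw differences of ROI relative powers, right minus left, for the
three homologous pairs (RMFC−LMFC, RMOC−LMOC, RT−LT) over theta…beta3 —
the raw-difference convention (rather than the log-ratio alpha-asymmetry
convention) because the quantities being compared are already normalized
fractions, and delta is excluded to mirror the standard reporting layout of
such tables.

## Preprocessing

The chain has a fixed order: band-pass → notch → downsample → ICA ocular
removal → 2-s epoching → amplitude rejection → average re-reference.
Rejection deliberately precedes re-referencing so that a single channel's
excursion cannot be smeared across the montage by the average reference.

**Filters.** All temporal filters are zero-phase Hamming windowed-sinc FIR
filters applied by FFT convolution with the group delay removed and mirror
padding at the edges. A windowed-sinc design keeps the passband flat (the
band-pass is within ±0.5 dB over 2–35 Hz), which low-order IIR designs
cannot achieve near their corners — a 4th-order Butterworth applied
forward–backward is already ≈2.4 dB down at 35 Hz with a 40 Hz corner. FIR
filtering is also what the major EEG toolboxes do by default. The band-pass
taps are DC-corrected (mean-subtracted) so a constant offset is nulled
exactly rather than attenuated by the window's finite stopband. The notch
widens its stop band by the transition width internally so the printed
49–51 Hz band is attenuated by ≥20 dB while 45 Hz changes by <3 dB.
Transition bandwidth is 2 Hz (filter length ≈ 3.3/2 × sampling rate,
rounded odd).

**Downsampling** is integer decimation, valid because the signal is already
band-limited to 40 Hz, far below the target Nyquist frequency.

**ICA ocular removal** uses a compact FastICA (symmetric orthogonalization,
logcosh contrast, PCA whitening, deterministic seeding) written for this
package. Components are flagged as ocular when their time course correlates
(|r| > 0.7) with the mean of Fp1/Fp2, or when their mixing weights are
frontopolar-dominated (both |w(Fp1)| and |w(Fp2)| above 3× the median
absolute weight); flagged sources are zeroed and the signal reconstructed.
On near-Gaussian background activity the symmetric FastICA rotation has no
unique optimum, so the iteration cap (200) is often reached without formal
convergence; the final iterate is still a valid orthogonal unmixing and is
used, with the convergence flag recorded. Only a numerical failure triggers
a pass-through, and never silently. Whether ICA is run on continuous or
epoched data is not standardized in the literature; it runs on continuous
data here, the common choice.

**Rejection** drops any epoch containing a sample strictly beyond ±150 μV
("beyond" read strictly: a sample at exactly 150 μV is retained — the
boundary is irrelevant in practice and fixed only for determinism), logging
the offending channel and peak amplitude, and never modifying sample
values.

## The synthetic cohort generator

Every channel is a stationary Gaussian process whose power spectrum is the
sum of a 1/f^χ background (default χ = 1.3, broadband RMS 4 μV over
1–40 Hz) and six band-limited components. The process is synthesized in the
frequency domain — a Hermitian complex Gaussian spectrum shaped by the
target PSD, inverted by FFT — which is distributionally identical to
filtering white noise through the corresponding filters (a Gaussian process
is fully determined by its mean and PSD) and an order of magnitude faster,
which the repeated-cohort validations require. Band component profiles are
flat-top raised-cosine windows whose 1 Hz roll-offs lie entirely inside the
band, so a component deposits power only in its own band; this makes the
zero-sum structure of relative power exact — raising one band's amplitude
strictly raises its relative power and strictly lowers all others'.

Base oscillation amplitudes vary by scalp region class (frontal/central/
posterior) with posterior-dominant alpha; eyes-closed recordings multiply
posterior alpha amplitude by the alpha-reactivity ratio (default 1.5; half
strength elsewhere). Between-subject variability enters through trait-like
log-normal amplitude factors shared across both eye states: a global
per-band factor (log-SD 0.20), a per-channel-by-band factor (log-SD 0.11)
and a background factor (log-SD 0.10). These SDs were chosen once so that
the configured group effects produce cohort-level Cohen's d in the 0.3–0.8
range at 40 subjects per group — the magnitude regime of the study design
the generator emulates.

Group effects are multiplicative amplitude factors on ROI/band targets
(eyes-open frontal beta2 elevation in patients as the dominant contrast,
plus central beta2 elevation, occipital beta3 reduction, eyes-closed RMFC
beta2 and right-temporal alpha elevation, right-occipital beta3 reduction);
a channel shared between several targeted ROIs receives the mean of their
multipliers, resolving the ROI overlap ambiguity. Hemispheric asymmetry
shifts scale the right ROI's channel amplitudes by 1 + s/2 and the left's
by 1 − s/2. Both groups carry baseline shifts so that controls too have
nonzero asymmetries, as real cohorts do.

Artifacts: blinks are 0.3–1 s smooth positive bumps of 100–300 μV at
Fp1/Fp2 decaying posteriorly over the scalp; excursion bursts are 0.2–0.5 s
bumps of 250–400 μV on one random channel. Excursions are placed wholly
inside one 2-s analysis epoch with peaks far beyond the rejection
threshold, so the set of epochs a rejection stage must drop is exactly
determined by the ground-truth table — this is what makes the
sensitivity = specificity = 1 recovery property well-defined rather than
dependent on how a burst's smooth tail straddles an epoch boundary.

The severity score (HDRS-17, patients only) is 17 plus a component driven
by the subject's latent frontal beta2 amplitude factor plus Gaussian noise,
floored at the inclusion threshold of 17; defaults give a patient mean near
24.1, SD near 4.8, and a cohort-level Pearson r ≈ 0.2 between the score and
observed eyes-open PFC beta2 relative power (target r ≈ 0.23).

**What the generator does not emulate:** volume conduction from discrete
cortical sources (no head model), non-stationarity (drowsiness, vigilance
drift), medication or comorbidity effects, heavy-tailed muscle/EMG
contamination, and line noise. Passing tests therefore demonstrate that the
pipeline recovers the statistical structure it targets under a stationary
Gaussian model of EEG — not that it is robust to every failure mode of real
recordings.

## Inferential layer

Group contrasts use Welch's t-test by default (group variances differ in
this kind of data; the pooled variant is available and the two agree
exactly for equal sizes and variances). Cohen's d uses the (n−1)-weighted
pooled SD under the control-minus-patient sign convention: positive d means
the control mean is larger. FDR correction is Benjamini–Hochberg step-up,
applied within four families: per eye state, separately for the 60 power
features and the 15 asymmetry features — the narrowest family structure
consistent with reporting adjusted values per condition. Demographic 2×2
tables use the Pearson chi-square without continuity correction.
Correlations with clinical scores are Pearson product-moment within the
patient group.

## Diagnostic model

The diagnostic model is an unpenalized binary logistic regression on raw
(unstandardized) relative-power and asymmetry features plus an intercept —
raw scale because the coefficients of interest are per unit of
relative-power fraction, which is how such models are conventionally
reported. The default feature set is a declarative 18-feature list (the
eyes-open frontal/central beta2 and occipital beta3 powers with temporal
asymmetries; the eyes-closed regional powers and temporal asymmetries).
Complete or quasi-separation (non-convergence, diverging coefficients, or
fitted probabilities at machine 0/1) triggers a ridge-stabilized IRLS refit
(λ = 1e-4) and flags the report.

Performance is estimated by stratified 10-fold cross-validation with a
mandatory, logged seed: per fold, the model is fit on the training
subjects, fold AUC is the trapezoidal ROC integral over the held-out
scores, and fold sensitivity/specificity are measured on the held-out
subjects at the Youden cut-off derived from the *training* scores (deriving
the cut-off on the test fold would leak); values at the fixed 0.5
probability cut-off are reported alongside. ROC thresholds are the unique
score values plus a sentinel, with "score ≥ threshold ⇒ predicted
positive"; the AUC is identical to the Mann–Whitney U statistic divided by
the number of positive–negative pairs, and the Youden cut-off breaks ties
toward the lowest threshold (favouring sensitivity). The 95% CI for the AUC
is a percentile bootstrap (2000 resamples by default) over subjects,
stratified by class so every resample contains both classes; it is computed
on the pooled out-of-fold scores, one score per subject.

## Numerical and design choices

- Half-open band edges with the final band closed at 40 Hz prevent double
  counting at shared edges; without this the six fractions would not sum to
  one.
- Epochs are consecutive and non-overlapping; a trailing partial epoch is
  discarded.
- Seeded functions (cohort generation, artifact injection, ICA, CV splits,
  bootstrap) save and restore the caller's RNG state, so a seeded call
  never perturbs surrounding user code.
- All simulated cohorts, reports and file outputs are pure functions of
  their spec/configuration including seeds; outputs carry a configuration
  hash.
- The desk-scale default (40 subjects per group, 60 s per eye state at
  250 Hz) runs the full pipeline in seconds; the emulated acquisition
  protocol (600 s per eye state at 1000 Hz, 86/83 subjects) is available by
  overriding the spec.

## Validation problem sizes

The repeated-cohort validations in the test suite run the full downstream
pipeline (band-pass, epoching, ±150 μV rejection, average reference,
spectral features, Welch contrasts with BH-FDR, stratified 10-fold logistic
CV) on 20 effect cohorts and 30 null cohorts at the desk scale, with
artifact injection and ICA disabled there — those two stages are validated
by their own dedicated tests (exact ground-truth excursion recovery; blink
removal with preserved occipital alpha), and the calibration questions
concern the clean-signal path. White-noise spectral calibration uses 120
epochs; the BH-FDR and ROC/Youden oracle comparisons use 1000 random cases
each. `scripts/acceptance.R` re-runs the same computations at reduced
cohort counts (10 effect, 10 null) and writes the headline numbers as JSON.

## Known limitations

- The generator's Gaussian stationarity means amplitude-rejection
  false-positives on clean data are essentially impossible (background
  excursions beyond 150 μV would require ~15σ events); real EEG violates
  this routinely.
- ICA component identification is tuned to the frontopolar blink topography
  of the generator; lateral eye movements (which dominate at F7/F8) are not
  modelled and would need an additional criterion.
- With 18 features and 80 subjects the unpenalized logistic fit is close to
  its stability limit; the ridge fallback keeps reports finite under
  separation but its standard errors are then conditional on the penalty.
- The EDF writer/reader supports the 16-bit uV/mV single-rate subset of the
  format that this workflow needs, not the full standard.
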