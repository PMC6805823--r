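---
title: "Acoustic CAD-score construction, reclassification and evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic CAD-score construction, reclassification and evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonocad)
```

## The problem

Most patients referred for non-invasive testing with suspected stable
coronary artery disease (CAD) do not have obstructive disease. A cheap,
safe first-line rule-out test applied before imaging can therefore spare a
large fraction of referrals. The candidate examined here is an acoustic
score: weak diastolic murmurs from post-stenotic turbulent coronary flow
leave a spectral signature in a high-sensitivity phonocardiogram, and a
score built from that signature plus three clinical variables can be used
to reclassify intermediate-risk patients downward when it is low.

`phonocad` implements the full chain on synthetic data: no clinical
recordings are distributed, so a simulator with controlled ground truth
stands in for the cohort, and every statistical claim the package makes is
one its own tests compute.

## The synthetic cohort

`cohort_config()` fixes the study conditions. Defaults describe a pooled
referral population: age 58.3 ± 8.4 years (truncated to 20–86), 52.8%
female, 58.5% hypertensive, BMI 26.9 ± 4.2, 5.3% diabetic, symptom mix
21.8/27.1/28.9/22.2% (typical/atypical/non-specific/none), and a disease
mix of 46.4% non-CAD, 44.2% mild-CAD, 9.4% significant-CAD. Disease level
is drawn first; age, sex and hypertension are then drawn from
level-conditional distributions (age shifts of −1.2/+0.8/+2.2 years,
male odds multipliers 1/1.25/1.9, hypertension odds 1/1.3/1.7) whose
baseline is solved numerically so the cohort marginals still match the
configured values. Sicker patients are thus older, more often male and
more often hypertensive, giving the clinical covariates genuine predictive
value in the fusion model, without distorting the baseline table.

Symptoms are drawn independently of disease level; this is a simplification
(in referral populations typical angina predicts stenosis), so the
synthetic pre-test probability discriminates mainly through its age and sex
terms.

## The phonocardiogram simulator

Each patient receives a 150 s recording at 1000 Hz preceded by a 30 s
pre-test sound-check segment. Per beat the simulator places an S1 and an S2
transient — decaying oscillations around 30 Hz (decay 18 ms) and 55 Hz
(12 ms), with ±8% lognormal amplitude jitter and S2 at 65% of S1
amplitude. The heart rate is drawn per patient from a normal distribution
with mean 65 and SD 8 bpm truncated to 45–110; the systolic duration
follows the physiologic monotone map `0.35 s − 0.0012 s · (HR − 60)`; RR
intervals vary with a coefficient of variation of 0.03 (0.25 for the
configured 1.1% of arrhythmic patients, exercising the QC rejection path).

The murmur is band-limited Gaussian noise (200–500 Hz, raised-cosine band
edges) gated over each diastole with 10 ms ramps. Its per-patient RMS is
`0.05 × m(level) × Lognormal(0, 0.6)` with level multipliers
`m = (0.5, 0.72, 1.0)` for non/mild/significant CAD, on top of broadband
measurement noise of RMS 0.03 (S1 amplitude is 1). The lognormal spread is
what keeps the classes overlapping: with these values the fitted score
reaches an AUC near 0.75 on a large training cohort, matching the
discrimination reported for the clinical device, which is how the defaults
were chosen. A multiplier of zero switches the disease effect off entirely
— a null configuration the tests use.

The simulator is a statistical stand-in, not a hemodynamic model: real CAD
murmur amplitudes, bands and their coupling to stenosis geometry are not
publicly characterised, so passing tests demonstrate that the pipeline
recovers a planted band-limited diastolic effect, not that the specific
spectral shape matches the device's signal.

## Quality control and segmentation

`quality_check()` mirrors a device's pre-test validation with documented
defaults (the source protocol publishes none): minimum duration 30 s, at
least 20 detectable beats, S1 peak-to-background envelope ratio at least 2
(`noisy_or_weak` otherwise), and RR coefficient of variation at most 0.2
(`arrhythmia`).

`segment_heart_sounds()` uses a square-law energy envelope (40 ms centred
moving average) of the 20–80 Hz band, where S1/S2 live and the murmur band
cannot interfere. Peak picking is followed by a duration-constrained
dynamic-programming decoder: the S1 chain is the path through candidate
peaks maximising summed envelope height subject to successive gaps near a
small multiple of the RR interval estimated from the envelope
autocorrelation (lag search 0.45–1.5 s); S2 is the tallest candidate in the
systolic window after each S1, and a short-gap/long-gap test decides
whether the chain caught S1s or S2s. Onsets are refined by cross-correlating
each beat's envelope against the median beat template and reading the
threshold crossing (15% of flank height) off the template once, with a
28 ms envelope-lead correction (half the smoothing window plus the
transient rise time). This decoder was chosen over a full hidden
semi-Markov model as the simplest design meeting the package's accuracy
contract: on clean defaults every annotated S1 onset is recovered within
20 ms, above 95% are recovered down to an envelope peak-to-background SNR
of roughly 12 dB, and accuracy degrades monotonically with SNR — a
property the tests check. Intervals use the half-open `[onset, offset)`
convention in seconds from recording start, and S1 + systole + S2 +
diastole tile each RR interval exactly.

## The acoustic model

Eight features, each the median over beats (per-beat aggregation is
unpublished for the device; the median is a robust documented stand-in),
all invariant to overall amplitude scaling: the log diastolic and systolic
murmur-band power ratios, diastolic spectral entropy, the dominant AR(4)
pole frequency of diastole (Yule-Walker), the log diastolic/systolic RMS
ratio, the log S1/S2 envelope amplitude ratio, the diastolic
high-frequency (> 250 Hz) energy fraction, and the beat-to-beat IQR/median
of diastolic murmur-band power. Band powers come from FFT band selection
with cumulative-sum interval sums; spectral features from one FFT over a
per-beat window matrix (Hann window, up to 512 samples of each diastole).

The features feed a two-class Fisher discriminant with the pooled
within-class covariance shrunk 10% toward its diagonal (and a tiny ridge if
a feature is constant), so duplicated or collinear features never break the
fit; in the unregularised limit the direction agrees with the classical
LDA solution, which the tests verify against an independent implementation.

## Logistic fusion, scaling and the threshold

The acoustic score is fused with age (years, untransformed), sex
(male = 1) and hypertension (systolic blood pressure ≥ 140 mmHg or on
antihypertensive treatment) by maximum-likelihood logistic regression
(tolerance 1e-8). Constant predictors are dropped with a warning; perfect
separation triggers a flagged ridge fallback (penalty 1e-4) so the
pipeline never returns infinite coefficients.

The linear predictor is mapped to the 0–99 display scale by an affine map
with two anchors. Scores are rounded half-up to integers and clamped to
0–99 (such devices display integers; whether the original score is
integer-valued is unstated), and the 90% rule-out guarantee refers to the
displayed score. The defining anchor therefore places the empirical 10th
percentile (linear-interpolation quantile) of the diseased training
patients' linear predictors at the very top of the threshold's rounding
bin: the anchor itself still displays 20, while every diseased patient
above it displays a score greater than 20, so 90% of diseased training
patients score above the threshold after rounding (had the anchor mapped
to the continuous value 20 instead, the patients whose raw score lands
between 20 and 20.5 would round down and the realised fraction would fall
a percent or two short). The slope anchor is a design choice the source
leaves open: the 2.5th–97.5th percentile span of all training linear
predictors maps onto scores 5–75, filling the display range without
saturating it; both anchors are configurable. A score above 20 is
`abnormal`; 20 itself is `normal` — the rule-out side.

## Pre-test probability and reclassification

The PTP model is a logistic function of age, sex and symptom typicality in
the updated Diamond-Forrester form. The original coefficients are not
published in the source; the shipped defaults are a synthetic stand-in
fitted once to the widely reproduced guideline PTP table (30 age/sex/symptom
cells, reproduced within half a percentage point) and frozen. Every
coefficient is configurable, including a separate one for non-specific
symptoms (mapped to the non-anginal reference by default) and for
asymptomatic patients; unit tests use toy coefficients only, so nothing in
the test suite depends on the stand-in values.

Bands are low < 15%, intermediate 15–85% (both edges inclusive to
intermediate, following the guideline wording), high > 85%. The scheme is
deliberately down-only: intermediate patients with a score ≤ 20 move to
low; nobody moves up; low and high pass through. The binary net
reclassification index is
`NRI = (up_e − down_e)/events + (down_ne − up_ne)/non-events`
with the upward terms structurally zero. Asymptomatic patients are
excluded from the reclassification analysis by default, mirroring a
referral population of symptomatic patients.

## Diagnostic statistics

All proportions carry exact Clopper–Pearson 95% intervals — the exact
method is the package default because it reproduces published interval
bounds for the sensitivity of the score that the Wilson interval does not,
and it stays conservative (coverage ≥ 95%, verified by simulation). The
chi-square test is Pearson's without continuity correction (again matching
the published p-value for the low-group event comparison). ROC/AUC use the
Mann-Whitney tie convention; the paired AUC comparison is DeLong's test,
the unpaired one a z-test with Hanley–McNeil variances. Bayesian post-test
probabilities are pre-test odds times likelihood ratio; the identities
`post(prev, PLR) = PPV` and `1 − post(prev, NLR) = NPV` hold to machine
precision and are enforced as invariants. Reported values round to one
decimal for percentages, two for likelihood ratios, three for the NRI.

## Cross-validation

`repeated_cv()` re-trains both the discriminant and the logistic fusion in
a repeated stratified k-fold design (default 50 × 10-fold; repeat r uses
seed + r). Out-of-fold scores are pooled per repeat before the AUC —
whether the original analysis pooled or averaged fold AUCs is unstated;
pooling is the package default and the alternative is a switch. Folds are
stratified by disease status and re-drawn (logged) in the rare case a
training fold lacks events. With `folds = n` the machinery reduces to
leave-one-out, which the tests pin against a brute-force oracle.

## Numerical and scale choices

Sampling rate defaults to 1000 Hz — twice the murmur band's upper edge.
FFT band selection uses raised-cosine transitions of 15 Hz; the
Butterworth `bandpass_filter()` (order 4, applied forward-backward for
zero phase) serves where a causal-style filter object is wanted.
Simulation-based checks in the test-suite run at reduced problem sizes
chosen for tight feedback loops (cohorts of a few hundred patients with
20–60 s recordings); the reference training run used by the acceptance
checks is a full n = 2000 cohort at the default 150 s protocol with
ground-truth (annotation-driven) segmentation, the detector being
validated separately on its own accuracy contract.

## Known limitations

The simulator omits ECG, respiration, valve pathology murmurs and
real-world noise nonstationarity; symptoms are independent of disease; the
PTP defaults are a calibrated approximation, not the original regression;
and the eight-feature bank is a documented stand-in for a proprietary
feature set of which only the count and structure are public. Results on
synthetic data therefore validate the pipeline's statistical machinery and
internal consistency, not clinical performance.
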