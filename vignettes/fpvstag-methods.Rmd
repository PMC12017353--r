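---
title: "Quantifying frequency-tagged scene discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying frequency-tagged scene discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvstag)
```

# The measurement problem

Fast periodic visual stimulation (FPVS) presents images at a fixed rate so
that the neural response becomes frequency-locked to the stimulation and
measurable as narrow spectral peaks. Two designs are implemented here:

* **Oddball**: neutral scenes at a 5 Hz base rate, with a negative scene
  replacing every fourth image. Any neural response at 5/4 = 1.25 Hz and its
  harmonics can only arise if the brain discriminates the deviant category
  from the base category — an implicit, no-task index of negative-vs-neutral
  scene discrimination.
* **Multi-input**: two simultaneous streams (one negative, one neutral
  scene stream) tagged at 4.61 Hz and 5 Hz in the left and right visual
  field. The relative amplitude at each tag indexes the neural salience of
  that stream under direct competition.

The package quantifies these responses, assigns concurrently recorded
fixations to stimulus regions, and models subject-level summaries across a
two-group cohort (young adults with and without childhood-adversity
exposure). A synthetic-data generator emulates all three data modalities
with known ground truth, so every stage of the pipeline is testable without
any recorded data.

# Spectral statistics

`compute_spectrum()` applies an FFT after per-channel mean removal — no
other detrending — and scales amplitudes by 2/N so a sinusoid of amplitude
*a* µV reads *a* µV at its bin. Recordings carrying several stimulation
sequences (epochs) are averaged coherently in the time domain first, the
standard FPVS practice: phase-locked signal is preserved while
non-phase-locked noise shrinks with the square root of the epoch count.

At a target bin, all three response statistics are referenced to the 20
surrounding bins (10 per side, skipping the bin immediately adjacent on
each side, which may carry spectral leakage; both counts are configurable):

* SNR = amplitude / mean(neighbours) — used for visualization;
* baseline-subtracted amplitude = amplitude − mean(neighbours), in µV —
  the quantity summed over harmonics and modelled;
* z = (amplitude − mean) / sd(neighbours), with the sample (n − 1) SD —
  used for harmonic selection against the one-sided 5% normal critical
  value `qnorm(0.95)` (1.64).

Degenerate neighbourhoods yield sentinels with warnings (`Inf` SNR for a
zero neighbour mean, signed-`Inf` z for a zero neighbour SD) rather than
silent numbers.

Bin alignment is strict: `target_bin()` errors when a requested frequency
is further than a quarter bin from a bin centre, because silently snapping
can misattribute a response to a neighbouring frequency. The *simulator*,
in contrast, snaps its stimulation rates onto the bin grid and records the
snapped value: the 4.61/5 Hz pair cannot both be exact bins for an
arbitrary duration, and at the default 60 s sequence length 4.61 Hz is
realised as 277/60 ≈ 4.6167 Hz. Harmonics are generated from the snapped
fundamental so that every harmonic is itself an exact bin multiple.

# Harmonic summation

`enumerate_harmonics()` builds each response's candidate set: ascending
integer multiples of the fundamental, excluding any multiple that
coincides with a multiple of the base rate (decided by exact rational
comparison of harmonic indices, never floating-point equality of
frequencies). For the 1.25 Hz oddball response this yields 1.25, 2.5,
3.75, 6.25 and 7.5 Hz — the 4th multiple, 5 Hz, carries the general visual
response to the base stream and is excluded. The multi-input streams use
the first four harmonics each (up to 18.44 and 20 Hz).

`select_significant()` implements the inclusion rule: harmonics are scanned
in ascending order on group-averaged, ROI-averaged spectra, and the
retained prefix ends before the first run of two consecutive harmonics
whose z fails the 1.64 threshold in *any* ROI × group × content cell; the
prefix is trimmed to end on a significant harmonic. A stricter variant
(`mode = "strict"`) additionally drops isolated non-significant harmonics
inside the prefix. Group-averaged spectra are used because single-subject z
values at weak harmonics are noisy; this mirrors how harmonic counts are
fixed per study, not per subject.

`summed_response()` then sums baseline-subtracted amplitudes over the
retained harmonics per channel and averages channels within each region of
interest (LOT: P7, P9, PO7; MO: Iz, Oz, O1, O2; ROT: P8, P10, PO8). All
three operations are linear, so their order cannot change the value; the
fixed order (subtract, sum, average) makes per-channel diagnostics
reproducible.

**A note on bias.** Baseline-subtracted amplitude is a biased estimator at
finite SNR: the target bin holds |signal + noise| while the local noise
mean is subtracted in amplitude units, so each summed harmonic loses
roughly the noise-floor mean amplitude. With the default noise model and a
single 60 s sequence this amounts to ≈ 15% of a 1 µV summed response;
coherent averaging of the default four sequences halves the noise floor
and brings recovery within 10%. This is a property of the estimator
itself, shared with its use in practice, and is why the simulator's
default `n_epochs = 4` matters for quantitative recovery.

# Gaze weighting

Fixations are assigned to the two stimulus rectangles by probability
weighting rather than all-or-nothing containment: each fixation is treated
as an isotropic bivariate Gaussian centred on its reported position with
SD equal to the subject's calibration validation error, and each AOI
receives the Gaussian mass over its rectangle (a product of two normal
interval masses). The remainder goes to an explicit "outside" region, so
the three proportions always sum to 1. As the calibration error shrinks,
the weights converge to point-in-rectangle assignment; subjects with
poorer calibration contribute softer assignments. Proportional looking
time per AOI is the fixation-duration-weighted average of these weights.
The kernel and its SD multiplier are configurable.

# The cohort models

Subject × condition summaries are modelled with random-intercept linear
mixed models fitted by REML (lme4/lmerTest), with type-III F tests using
the Satterthwaite denominator-df approximation and sum-to-zero contrasts
on all factors (type-III tests are contrast-dependent; this is the
convention of the mixed-model tooling this pipeline follows). Post-hoc
cell-mean comparisons are Tukey-corrected via emmeans.

Three specifications per outcome, as `model_spec()` documents: Model 1
contrasts the groups (`y ~ age + sex + Group*Content*ROI + (1|subject)`
for the oddball outcome; Valence replaces ROI for the multi-input
outcomes); Models 2 and 3 are fitted within the adversity group only and
enter childhood adversity (Model 2) or its threat and neglect dimensions
(Model 3) plus depression, anxiety and psychosis scores as standardized
(M = 0, SD = 1) continuous predictors in interaction with the
within-subject factors. The implementation refuses to fit Models 2-3 on
tables containing control-group rows.

Before fitting, outcomes are screened per analysis cell (content × ROI for
the oddball outcome; valence × content × rate for the multi-input
outcomes) with the median-absolute-deviation rule: a point is removed when
|x − median| exceeds 3 robust SDs (raw MAD × 1.4826). Both constants are
configurable and reported; removal counts are logged in the returned
table's attributes.

`gaze_neural_correlation()` relates the two modalities: per subject and
content, the negative-minus-neutral difference score of the gaze
proportions and of the neural salience, correlated (Pearson, df = n − 2)
across subjects per content context.

# What the generator emulates — and what it does not

`sim_config()` holds every tunable with units and defaults. The main
choices:

* **EEG signal**: stationary sinusoids at tagged frequencies and harmonics
  with per-ROI gain maps. Only harmonic content matters to the analysis,
  so no attempt is made to model waveform shape, evoked transients, or
  trial-to-trial latency jitter.
* **Noise**: a 1/f amplitude profile (0.08 µV at 1 Hz, exponent 1) plus
  white noise (SD 1 µV), independent across channels. This reproduces the
  spectra the statistics operate on without claiming physiological
  fidelity (no alpha peak, no line noise, no artifacts); SNR at the
  oddball fundamental is ≈ 3-4 on a single sequence, in the range typical
  of these paradigms.
* **Sequences**: 60 s per sequence (frequency resolution 1/60 Hz), four
  sequences per condition, coherently averaged. Trial counts are rarely
  printed for such designs; four is typical of the closely related
  face-discrimination paradigms.
* **Cohort**: 43 controls and 48 adversity-exposed subjects (the EEG
  sample sizes modelled here), female-majority (75%), with the adversity
  group slightly older. Threat and neglect scores are near zero in
  controls and gamma-distributed in the adversity group; the composite
  adversity score is their 5:2 category-weighted mean; symptom scores
  load on a shared severity factor correlated with exposure. Effects are
  parameterized in units of the within-subject SD: the control group
  carries a social-vs-nonsocial content gap of 1 within-SD (the adversity
  group none), threat reduces the content effect within the adversity
  group, neutral streams out-compete negative streams (more in the social
  context), and higher adversity shifts gaze relatively towards negative
  scenes. A per-subject latent valence-sensitivity factor, correlated
  0.95 between the neural and gaze outcomes, induces the gaze-neural
  correlation; with the default reliabilities the observable r per context
  is ≈ 0.65-0.75 (classical attenuation:
  r = loading × sqrt(rel_neural × rel_gaze)).
* **Fixations**: dwell probabilities per AOI, centre-biased landing points
  (truncated Gaussian, SD one sixth of the rectangle — scene fixations
  cluster on image centres, and uniform landing points would put true
  fixations on the border where calibration scatter leaks mass across the
  AOI boundary), isotropic Gaussian calibration noise, gamma-distributed
  durations.

Passing tests on these simulations demonstrate that the pipeline recovers
what it is pointed at under its own assumptions; they cannot certify
robustness to artifacts, preprocessing choices, or non-stationary
responses, which are outside the generator's vocabulary.

# Numerical and design choices

* Seeds: every generator derives its RNG stream deterministically from the
  configuration seed plus subject/condition identifiers, so runs are
  bit-reproducible and subjects independent.
* The sample SD (n − 1) is used both for the neighbour-bin z and for
  standardization.
* MAD = 0 cells produce a warning and no flags (rather than flagging every
  non-median point).
* Rank-deficient fixed-effect designs and non-converged fits are errors
  naming the aliased terms, not silent drops. With very small groups
  (fewer than ~10 adversity subjects) Models 2-3 are intentionally
  rank-deficient: they carry seven between-subject predictors.
* The mixed-model F tests reduce exactly to the balanced fixed-effects
  ANOVA when the random-intercept variance is estimated at zero; this
  anchor is tested against a closed-form sums-of-squares oracle.
* Problem sizes in the test-suite: the spectral null calibration uses
  16 noise-only recordings of 20 s (≈ 5400 evaluated bins); signal
  recovery averages 100 seeded replicates at the default 60 s × 4
  sequences; model sign-recovery and type-I calibration each use 200
  cohort replicates at the full 43/48 group sizes.

# Known limitations

* EEG preprocessing (filtering, artifact rejection, re-referencing) is out
  of scope; the pipeline consumes cleaned or synthetic recordings.
* The gaze module consumes fixation tables; event detection from raw gaze
  samples is not implemented.
* Cohort-level test statistics (specific F and r values) from any recorded
  dataset depend on that data; the pipeline reproduces the analysis
  constants and the qualitative effect structure, not dataset-specific
  numbers.
* Proportional looking times are modelled on the proportion scale with
  Gaussian errors, adequate away from the 0/1 boundaries but not a
  compositional model.
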