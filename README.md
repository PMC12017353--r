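# fpvstag

Frequency-tagging EEG and eye-tracking analysis of negative-vs-neutral
scene processing, with a fully synthetic validation harness.

## What this package is for

Fast periodic visual stimulation (FPVS) presents images at fixed rates so
that neural responses become frequency-locked and measurable as narrow
spectral peaks. Two paradigms are supported:

* **Oddball** — neutral scenes at a 5 Hz base rate with a negative scene
  every fourth image: a response at 1.25 Hz (= 5/4) and its harmonics
  indexes implicit discrimination of negative from neutral scenes.
* **Multi-input** — simultaneous negative and neutral streams tagged at
  4.61 and 5 Hz: the relative tagged amplitudes index each stream's
  neural salience, alongside preferential looking measured by eye
  tracking.

The package implements the full quantification and inference chain used in
this literature, aimed at researchers analysing such experiments (or
planning them via simulation):

1. **Spectral statistics.** Single-sided FFT amplitude spectra (a sinusoid
   of amplitude *a* µV reads *a* µV at its bin), and per-bin statistics
   against the 20 surrounding frequency bins:
   `SNR = a / mean(neighbours)`, baseline-subtracted amplitude
   `a − mean(neighbours)` (µV), and `z = (a − mean) / sd(neighbours)`.
2. **Harmonic summation.** Candidate harmonics per response (oddball:
   1.25–7.5 Hz excluding the 5 Hz base-rate coincidence; multi-input: four
   harmonics per stream, up to 18.44 / 20 Hz), significance selection at
   z > 1.64 (one-sided 5%) requiring two consecutive failures to stop, and
   summed baseline-subtracted responses averaged over occipito-temporal
   ROIs (LOT, MO, ROT).
3. **Gaze weighting.** Probability-weighted fixation-to-AOI assignment: an
   isotropic Gaussian with SD equal to the subject's calibration error is
   integrated over each stimulus rectangle, and proportional looking times
   are duration-weighted averages of these weights.
4. **Cohort inference.** MAD outlier screening per analysis cell,
   standardized continuous predictors, three random-intercept linear
   mixed-model specifications per outcome
   (`y ~ age + sex + Group*Content*ROI + (1|subject)` and the
   within-adversity-group adversity/threat/neglect models) with type-III
   Satterthwaite F tests, Tukey-corrected post-hoc contrasts, and the
   per-context correlation between gaze and neural valence-difference
   scores.
5. **Synthetic data.** Generators for EEG (tagged sinusoids + 1/f and
   white noise, ROI topographies, multi-sequence epochs), fixation
   streams, and a two-group cohort with configurable effect sizes — so the
   whole pipeline validates end-to-end against known ground truth.

## Worked example

Simulate a small cohort end-to-end (EEG synthesis → spectra → harmonic
selection → summed responses → mixed models) and inspect the
group-by-content interaction:

```r
library(fpvstag)
config <- analysis_config(
  sim_config(n_control = 12, n_adversity = 12, seed = 7, duration_s = 20)
)
run <- run_oddball(config)
run$models$model_1
#> <lmm_result> Model 1 (oddball), type-III F (Satterthwaite df):
#>                term         F df1 df2         p
#> 1               age 6.778e+00   1  20 1.700e-02
#> 2               sex 1.525e+00   1  20 2.312e-01
#> 3             group 3.372e-01   1  20 5.679e-01
#> 4           content 1.408e+02   1 110 2.078e-21
#> 5               roi 1.672e+01   2 110 4.579e-07
#> 6     group:content 1.411e+02   1 110 1.931e-21
#> ...

run$harmonics$selection$retained
#> [1] 5

tukey_contrasts(run$models$model_1, ~ content | group)
#> # A tibble: 2 x 7
#>   contrast           group      estimate     SE    df         t  p_tukey
#> 1 nonsocial - social adversity  0.000291 0.0294  110.   0.00991 9.92e- 1
#> 2 nonsocial - social control   -0.493    0.0294  110. -16.8     4.00e-32
```

Read: all five oddball harmonics pass the z > 1.64 selection rule; the
generator injected a social-minus-nonsocial discrimination advantage of
0.5 µV in controls and none in the adversity group, and the fitted model
recovers exactly that pattern — a strong group × content interaction
driven by the control group's social contrast (−0.493 µV, p ≈ 1e−32)
with a null contrast in the adversity group. `run_multiinput()` is the
analogous driver for the simultaneous-stream paradigm, adding gaze models
and the gaze-neural correlation per content context.

A thin command-line front end is included at
`inst/scripts/fpvstag.R` (`simulate`, `run-oddball`, `run-multiinput`,
`run-all`; flags `--config <yaml> --seed <int> --out <dir>`).

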