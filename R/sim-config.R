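#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: the EEG signal
#' and noise model, the per-subject variability, the cohort structure and the
#' effect sizes the cohort-level models are expected to recover, and the
#' fixation-stream geometry. All amplitudes are in microvolts; all effect
#' sizes for modelled outcomes are expressed in units of the within-subject
#' residual SD so that "an effect of 1" means one within-subject SD.
#'
#' @param duration_s Length of one stimulation sequence in seconds. The
#'   default of 60 s gives a frequency resolution of 1/60 Hz, on which every
#'   stimulation frequency used here falls exactly on (or is snapped to) an
#'   FFT bin.
#' @param n_epochs Stimulation sequences (trials) per condition. Each epoch
#'   repeats the same phase-locked signal with independent noise;
#'   [compute_spectrum()] averages epochs coherently in the time domain, the
#'   standard FPVS practice that lowers the noise floor by the square root of
#'   the epoch count. Trial counts are rarely printed; 4 sequences per
#'   condition is typical of this family of paradigms.
#' @param sampling_rate_hz EEG sampling rate.
#' @param channels Channel labels of the simulated montage; must contain all
#'   ROI channels of [roi_definitions()].
#' @param oddball_uv Amplitudes (µV) injected at the oddball harmonics
#'   (excluding any harmonic coinciding with the base rate), in ascending
#'   harmonic order.
#' @param base_uv Amplitudes (µV) injected at the base-rate harmonics.
#' @param stream_uv Amplitudes (µV) injected at the harmonics of each
#'   multi-input stream (same length for both streams).
#' @param roi_gains Named numeric topography gains; names are ROI names plus
#'   `"other"` for channels outside every ROI. Injected amplitudes on a
#'   channel are multiplied by its ROI's gain.
#' @param noise_white_sd_uv SD (µV) of the white time-domain noise.
#' @param noise_pink_scale_uv Single-sided spectral amplitude (µV) of the 1/f
#'   noise component at 1 Hz.
#' @param noise_pink_exponent Exponent of the 1/f^a amplitude profile.
#' @param subject_amp_sdlog SD of the log-normal per-subject multiplier
#'   applied to all injected signal amplitudes.
#' @param n_control,n_adversity Group sizes of the simulated cohort.
#' @param cohort_baseline_uv Grand-mean summed baseline-subtracted response.
#' @param between_sd,within_sd Between-subject (random intercept) and
#'   within-subject (residual) SDs of the modelled outcomes.
#' @param group_content_gap Content effect (social minus non-social) in the
#'   control group for the oddball outcome; the adversity group's content
#'   effect is 0, so this is also the group-by-content interaction gap.
#' @param roi_effect_scale Multiplier on the fixed ROI and ROI-by-content
#'   structure of the oddball outcome (1 = the default mild lateralisation
#'   pattern, 0 = none).
#' @param threat_content_slope Change in the oddball content effect per SD of
#'   threat score (within the adversity group).
#' @param neglect_content_slope Same for the neglect score (opposite-signed
#'   modulation by default).
#' @param valence_effect Neural-salience main effect of valence
#'   (neutral minus negative) in the multi-input paradigm.
#' @param valence_content_interaction Extra neutral-minus-negative salience
#'   difference in the social relative to the non-social context.
#' @param neural_sens_sd SD (within-SD units) of the per-subject latent
#'   valence-sensitivity factor on the neural-salience outcome. Individual
#'   differences in the neutral-vs-negative response are what the gaze-neural
#'   correlation rests on.
#' @param gaze_valence_effect Proportional-looking-time main effect of valence
#'   (neutral minus negative), on the proportion scale.
#' @param adversity_valence_gaze_slope Increase in relative looking towards
#'   negative scenes (i.e. decrease of the neutral-minus-negative gaze
#'   difference, proportion scale) per SD of childhood-adversity score.
#' @param gaze_sens_sd SD (proportion scale) of the per-subject latent
#'   valence-sensitivity factor on the gaze outcome.
#' @param gaze_within_sd Within-subject residual SD of the per-cell gaze
#'   proportions.
#' @param gaze_baseline Mean proportion of looking time per stimulus AOI
#'   (the remainder is outside-AOI looking).
#' @param gaze_neural_loading Correlation between the neural and gaze latent
#'   valence-sensitivity factors; together with the measurement reliabilities
#'   it determines the observable gaze-neural correlation (classical
#'   attenuation: `r = loading * sqrt(rel_neural * rel_gaze)`).
#' @param female_ratio Proportion of female participants (adversity cohorts
#'   are typically female-majority).
#' @param n_fixations Fixations simulated per subject and condition.
#' @param calibration_error_px Mean per-subject eye-tracker validation error
#'   (isotropic SD, pixels); per-subject values are jittered around this.
#' @param dwell_probabilities Baseline probabilities that a fixation targets
#'   the negative AOI, the neutral AOI, or neither.
#' @param seed Integer seed fixing all draws of the generators.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' names(cfg)
#' @export
sim_config <- function(duration_s = 60,
                       n_epochs = 4,
                       sampling_rate_hz = 250,
                       channels = c(roi_channels(), "Pz", "POz"),
                       oddball_uv = rep(0.2, 5),
                       base_uv = c(1.0, 0.6, 0.4, 0.25),
                       stream_uv = c(0.6, 0.35, 0.2, 0.1),
                       roi_gains = c(LOT = 1, MO = 1.2, ROT = 1.1, other = 0.4),
                       noise_white_sd_uv = 1,
                       noise_pink_scale_uv = 0.08,
                       noise_pink_exponent = 1,
                       subject_amp_sdlog = 0.25,
                       n_control = 43,
                       n_adversity = 48,
                       cohort_baseline_uv = 1.5,
                       between_sd = 0.5,
                       within_sd = 0.5,
                       group_content_gap = 1,
                       roi_effect_scale = 1,
                       threat_content_slope = -0.5,
                       neglect_content_slope = 0.25,
                       valence_effect = 0.6,
                       valence_content_interaction = 0.3,
                       neural_sens_sd = 2,
                       gaze_valence_effect = 0.08,
                       adversity_valence_gaze_slope = 0.03,
                       gaze_sens_sd = 0.08,
                       gaze_within_sd = 0.05,
                       gaze_baseline = 0.42,
                       gaze_neural_loading = 0.95,
                       female_ratio = 0.75,
                       n_fixations = 100,
                       calibration_error_px = 35,
                       dwell_probabilities = c(negative = 0.35, neutral = 0.5,
                                               outside = 0.15),
                       seed = 20260925) {
  stopifnot(
    duration_s > 0, n_epochs >= 1, sampling_rate_hz > 0,
    all(oddball_uv >= 0), all(base_uv >= 0), all(stream_uv >= 0),
    noise_white_sd_uv >= 0, noise_pink_scale_uv >= 0,
    subject_amp_sdlog >= 0, between_sd >= 0, within_sd >= 0,
    n_fixations >= 1, calibration_error_px > 0
  )
  if (n_control < 2 || n_adversity < 2) {
    stop("Group sizes must be >= 2.")
  }
  missing_roi <- setdiff(roi_channels(), channels)
  if (length(missing_roi)) {
    stop("Channel layout is missing ROI channels: ",
         paste(missing_roi, collapse = ", "))
  }
  if (abs(sum(dwell_probabilities) - 1) > 1e-9) {
    stop("`dwell_probabilities` must sum to 1.")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Per-channel topography gains implied by the ROI gain map
#' @param cfg A [sim_config()].
#' @return Named numeric vector, one gain per channel in `cfg$channels`.
#' @keywords internal
channel_gains <- function(cfg) {
  gains <- rep(cfg$roi_gains[["other"]], length(cfg$channels))
  names(gains) <- cfg$channels
  for (roi in names(roi_definitions())) {
    chans <- intersect(roi_definitions(roi)[[1]], cfg$channels)
    gains[chans] <- cfg$roi_gains[[roi]]
  }
  gains
}
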