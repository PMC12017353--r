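#' Simulate a frequency-tagged EEG recording
#'
#' Synthesises a multichannel EEG recording whose frequency content realises
#' an FPVS paradigm: stationary sinusoids at every tagged stimulation
#' frequency and its configured harmonics, with ROI-specific topography
#' gains, superposed on a 1/f ("pink") plus white noise floor. Because the
#' frequency-tagging analysis quantifies responses purely in the frequency
#' domain, waveform shape beyond harmonic content is irrelevant and a
#' sinusoidal signal model is sufficient.
#'
#' Stimulation frequencies that do not fall exactly on the FFT bin grid of
#' the chosen duration are, by default, snapped to the nearest bin and the
#' snapped value is recorded in the returned paradigm (the 4.61 / 5 Hz
#' multi-input pair cannot both be exact bins for arbitrary durations; at the
#' default 60 s, 4.61 Hz becomes 277/60 = 4.6167 Hz). With `snap = FALSE` a
#' misaligned frequency is an error naming the offending frequency.
#'
#' All randomness (component phases, noise, the per-subject amplitude
#' multiplier) is drawn from a seed derived deterministically from
#' `cfg$seed`, `subject_id` and `condition`, so regeneration with the same
#' configuration is bit-identical and different subjects/conditions are
#' independent.
#'
#' @param paradigm An [oddball_paradigm()] or [multi_input_paradigm()].
#' @param cfg A [sim_config()].
#' @param subject_id Subject identifier (enters the derived seed).
#' @param condition Condition label; defaults to the paradigm's content.
#' @param oddball_total_uv Optional per-ROI named vector (or scalar) of total
#'   summed oddball response amplitudes in µV; when given, the configured
#'   per-harmonic oddball amplitudes are used only as a relative profile and
#'   scaled per channel so that the summed baseline-subtracted ROI response
#'   has this expected value (per-subject amplitude variability is then not
#'   applied to the oddball component). Used by the pipeline to inject
#'   cohort-level ground truth.
#' @param stream_total_uv Optional named list (one element per stream label)
#'   of the same form, for the multi-input streams.
#' @param snap Snap off-grid frequencies to the nearest bin (default) instead
#'   of erroring.
#' @return An object of class `eeg_recording`: list with `samples`
#'   (channels x time matrix in µV, or a channels x time x epochs array when
#'   `cfg$n_epochs > 1`), `channel_labels`, `sampling_rate_hz`,
#'   `duration_s`, `paradigm` (with snapped rates), `components` (tibble of
#'   injected frequencies and per-channel base amplitudes), `subject_id`,
#'   `condition`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' rec <- simulate_eeg(oddball_paradigm(), cfg, subject_id = "s01")
#' dim(rec$samples)
#' @export
simulate_eeg <- function(paradigm, cfg, subject_id = "s01",
                         condition = NULL,
                         oddball_total_uv = NULL,
                         stream_total_uv = NULL,
                         snap = TRUE) {
  stopifnot(inherits(paradigm, "fpvs_paradigm"), inherits(cfg, "sim_config"))
  condition <- condition %||% paradigm$content
  fs <- cfg$sampling_rate_hz
  n <- round(cfg$duration_s * fs)
  if (abs(n - cfg$duration_s * fs) > 1e-9) {
    stop("duration_s x sampling_rate_hz must be an integer sample count.")
  }
  res <- 1 / cfg$duration_s

  set.seed(derive_seed(cfg$seed, "eeg", subject_id, condition))
  subj_mult <- if (cfg$subject_amp_sdlog > 0) {
    exp(stats::rnorm(1, 0, cfg$subject_amp_sdlog))
  } else 1

  # snap the fundamentals first so every harmonic is an exact bin multiple
  # of the snapped rate (snapping harmonics individually would put them on
  # bins that are not multiples of the analysed fundamental)
  paradigm <- snap_paradigm(paradigm, res, snap)
  comp <- paradigm_components(paradigm, cfg)
  comp$freq_hz <- vapply(comp$freq_hz, snap_frequency, numeric(1),
                         resolution_hz = res, snap = snap)

  gains <- channel_gains(cfg)
  nch <- length(cfg$channels)
  # per-channel amplitude matrix: components x channels
  amp <- outer(comp$amplitude_uv, gains * subj_mult)
  if (!is.null(oddball_total_uv)) {
    amp[comp$role == "oddball", ] <-
      total_to_channel_amplitudes(comp$amplitude_uv[comp$role == "oddball"],
                                  oddball_total_uv, cfg)
  }
  if (!is.null(stream_total_uv)) {
    for (stream in names(stream_total_uv)) {
      sel <- comp$role == stream
      amp[sel, ] <- total_to_channel_amplitudes(comp$amplitude_uv[sel],
                                                stream_total_uv[[stream]], cfg)
    }
  }

  t_s <- (seq_len(n) - 1L) / fs
  phases <- stats::runif(nrow(comp), 0, 2 * pi)
  signal <- matrix(0, nrow = nch, ncol = n,
                   dimnames = list(cfg$channels, NULL))
  for (i in seq_len(nrow(comp))) {
    if (all(amp[i, ] == 0)) next
    wave <- sin(2 * pi * comp$freq_hz[i] * t_s + phases[i])
    signal <- signal + tcrossprod(amp[i, ], wave)
  }
  # each epoch repeats the phase-locked signal with fresh noise; coherent
  # epoch averaging in compute_spectrum then lowers the noise floor
  n_epochs <- as.integer(cfg$n_epochs %||% 1L)
  add_noise <- function(x) {
    if (cfg$noise_pink_scale_uv > 0) {
      for (ch in seq_len(nch)) {
        x[ch, ] <- x[ch, ] + pink_noise(n, fs, cfg$noise_pink_scale_uv,
                                        cfg$noise_pink_exponent)
      }
    }
    if (cfg$noise_white_sd_uv > 0) {
      x <- x + matrix(stats::rnorm(nch * n, 0, cfg$noise_white_sd_uv),
                      nrow = nch)
    }
    x
  }
  if (n_epochs == 1L) {
    x <- add_noise(signal)
  } else {
    x <- array(0, dim = c(nch, n, n_epochs),
               dimnames = list(cfg$channels, NULL, NULL))
    for (e in seq_len(n_epochs)) x[, , e] <- add_noise(signal)
  }

  structure(
    list(
      samples = x,
      channel_labels = cfg$channels,
      sampling_rate_hz = fs,
      duration_s = cfg$duration_s,
      paradigm = paradigm,
      components = tibble::tibble(
        role = comp$role, freq_hz = comp$freq_hz,
        amplitude_uv = comp$amplitude_uv, subject_multiplier = subj_mult
      ),
      subject_id = subject_id,
      condition = condition
    ),
    class = "eeg_recording"
  )
}

#' @exportS3Method base::print
print.eeg_recording <- function(x, ...) {
  n_ep <- if (length(dim(x$samples)) == 3L) dim(x$samples)[3] else 1L
  cat(sprintf(
    "<eeg_recording> %s / %s: %d channels x %d samples x %d epoch(s) @ %g Hz (%g s), %s paradigm\n",
    x$subject_id, x$condition, nrow(x$samples), ncol(x$samples), n_ep,
    x$sampling_rate_hz, x$duration_s, x$paradigm$paradigm_kind
  ))
  invisible(x)
}

# component table (freq, base amplitude, role) implied by paradigm + config
paradigm_components <- function(paradigm, cfg) {
  if (paradigm$paradigm_kind == "oddball") {
    odd <- enumerate_harmonics(paradigm$oddball_rate_hz,
                               n_keep = length(cfg$oddball_uv),
                               exclude_multiples_of_hz = paradigm$base_rate_hz)
    base <- enumerate_harmonics(paradigm$base_rate_hz,
                                n_keep = length(cfg$base_uv))
    data.frame(
      role = c(rep("oddball", length(odd$retained_hz)),
               rep("base", length(base$retained_hz))),
      freq_hz = c(odd$retained_hz, base$retained_hz),
      amplitude_uv = c(cfg$oddball_uv, cfg$base_uv)
    )
  } else {
    out <- lapply(names(paradigm$stream_rates_hz), function(stream) {
      h <- enumerate_harmonics(paradigm$stream_rates_hz[[stream]],
                               n_keep = length(cfg$stream_uv))
      data.frame(role = stream, freq_hz = h$retained_hz,
                 amplitude_uv = cfg$stream_uv)
    })
    do.call(rbind, out)
  }
}

# scale a harmonic profile so the per-ROI summed amplitude hits a target
total_to_channel_amplitudes <- function(profile_uv, total_uv, cfg) {
  profile <- if (sum(profile_uv) > 0) profile_uv / sum(profile_uv) else
    rep(1 / length(profile_uv), length(profile_uv))
  totals <- rep(NA_real_, length(cfg$channels))
  names(totals) <- cfg$channels
  if (length(total_uv) == 1 && is.null(names(total_uv))) {
    totals[] <- total_uv
  } else {
    for (roi in names(roi_definitions())) {
      chans <- intersect(roi_definitions(roi)[[1]], cfg$channels)
      totals[chans] <- if (roi %in% names(total_uv)) total_uv[[roi]] else
        mean(total_uv)
    }
    totals[is.na(totals)] <- cfg$roi_gains[["other"]] * mean(total_uv)
  }
  outer(profile, pmax(totals, 0))
}

#' Snap a frequency onto the FFT bin grid
#'
#' @param frequency_hz Frequency to align.
#' @param resolution_hz Bin width (1 / duration).
#' @param snap If `TRUE`, return the nearest bin centre; if `FALSE`, error
#'   unless the frequency is within `tolerance` bins of a centre.
#' @param tolerance Alignment tolerance as a fraction of the bin width.
#' @return The (possibly snapped) frequency in Hz.
#' @examples
#' snap_frequency(4.61, 1 / 60)       # 4.6167
#' snap_frequency(5, 1 / 60)          # exactly 5
#' @export
snap_frequency <- function(frequency_hz, resolution_hz, snap = TRUE,
                           tolerance = 0.25) {
  k <- round(frequency_hz / resolution_hz)
  snapped <- k * resolution_hz
  if (!snap && abs(frequency_hz - snapped) > tolerance * resolution_hz + 1e-12) {
    stop(sprintf(
      "Frequency %g Hz does not align with the %g Hz bin grid; choose a duration that makes it an integer bin multiple.",
      frequency_hz, resolution_hz
    ))
  }
  snapped
}

snap_paradigm <- function(paradigm, resolution_hz, snap) {
  if (paradigm$paradigm_kind == "oddball") {
    paradigm$base_rate_hz <- snap_frequency(paradigm$base_rate_hz,
                                            resolution_hz, snap)
    paradigm$oddball_rate_hz <- snap_frequency(paradigm$oddball_rate_hz,
                                               resolution_hz, snap)
  } else {
    paradigm$stream_rates_hz[] <- vapply(paradigm$stream_rates_hz,
                                         snap_frequency, numeric(1),
                                         resolution_hz = resolution_hz,
                                         snap = snap)
  }
  paradigm
}

# random-phase frequency-domain synthesis of a 1/f^a amplitude noise floor;
# scale_uv is the mean single-sided spectral amplitude at 1 Hz
pink_noise <- function(n, fs, scale_uv, exponent = 1) {
  n_half <- floor(n / 2)
  f <- (seq_len(n_half)) * fs / n
  mean_amp <- scale_uv / f^exponent
  # complex-Gaussian bins: E|z| for CN(0,1) is sqrt(pi)/2
  z <- complex(real = stats::rnorm(n_half), imaginary = stats::rnorm(n_half)) /
    sqrt(2)
  X <- numeric(0)
  coef <- mean_amp * n / 2 / (sqrt(pi) / 2)
  Xpos <- coef * z
  Xfull <- complex(real = numeric(n))
  Xfull[2:(n_half + 1)] <- Xpos
  if (n %% 2 == 0) {
    Xfull[n_half + 1] <- complex(real = Re(Xpos[n_half]), imaginary = 0)
    if (n_half > 1) Xfull[n:(n_half + 2)] <- Conj(Xpos[1:(n_half - 1)])
  } else {
    Xfull[n:(n_half + 2)] <- Conj(Xpos[1:(n_half - 1)])
  }
  Re(stats::fft(Xfull, inverse = TRUE)) / n
}

# stable small-integer seed derived from a base seed and string tokens
derive_seed <- function(base, ...) {
  s <- as.double(base %% 2147483647L)
  for (tok in c(...)) {
    for (code in utf8ToInt(as.character(tok))) {
      s <- (s * 31 + code) %% 2147483647
    }
  }
  as.integer(s)
}
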