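#' Amplitude spectrum of an EEG recording
#'
#' Transforms a (possibly windowed) multichannel recording to the frequency
#' domain with a fast Fourier transform and returns single-sided amplitudes.
#' The only detrending applied is per-channel mean removal; amplitudes are
#' scaled by 2/N so that a pure sinusoid of amplitude *a* µV reads *a* µV at
#' its bin (the DC bin keeps the 1/N scale). The frequency resolution is the
#' reciprocal of the analysed window length.
#'
#' When a recording carries multiple epochs (a third array dimension),
#' epochs are averaged in the time domain before the FFT, the usual coherent
#' averaging that preserves phase-locked periodic responses while attenuating
#' non-phase-locked noise.
#'
#' @param rec An [eeg_recording][simulate_eeg] (or any list with `samples`,
#'   `sampling_rate_hz`, `channel_labels`).
#' @param window Optional numeric `c(start_s, end_s)` restricting the analysed
#'   span; default is the whole recording.
#' @return An object of class `amplitude_spectrum`: list with
#'   `amplitudes_uv` (channels x bins matrix), `freq_resolution_hz`,
#'   `frequencies_hz`, `channel_labels`, `subject_id`, `condition`.
#' @examples
#' cfg <- sim_config(noise_white_sd_uv = 0, noise_pink_scale_uv = 0,
#'                   subject_amp_sdlog = 0, seed = 1)
#' rec <- simulate_eeg(oddball_paradigm(), cfg, subject_id = "s01")
#' sp <- compute_spectrum(rec)
#' sp$amplitudes_uv["Oz", target_bin(sp, 5) + 1L]
#' @export
compute_spectrum <- function(rec, window = NULL) {
  x <- rec$samples
  fs <- rec$sampling_rate_hz
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)  # average epochs
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[2] > window[1])
    i0 <- max(1L, floor(window[1] * fs) + 1L)
    i1 <- min(ncol(x), round(window[2] * fs))
    if (i1 < i0) stop("Requested window is empty.")
    x <- x[, i0:i1, drop = FALSE]
  }
  n <- ncol(x)
  if (n < 2) stop("Requested window is empty.")
  x <- x - rowMeans(x)
  n_bins <- floor(n / 2) + 1L
  amp <- t(apply(x, 1, function(ch) {
    a <- abs(stats::fft(ch))[seq_len(n_bins)] * 2 / n
    a[1] <- a[1] / 2
    if (n %% 2 == 0) a[n_bins] <- a[n_bins] / 2
    a
  }))
  rownames(amp) <- rec$channel_labels
  res <- fs / n
  structure(
    list(
      amplitudes_uv = amp,
      freq_resolution_hz = res,
      frequencies_hz = (seq_len(n_bins) - 1L) * res,
      channel_labels = rec$channel_labels,
      subject_id = rec$subject_id,
      condition = rec$condition
    ),
    class = "amplitude_spectrum"
  )
}

#' @exportS3Method base::print
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "<amplitude_spectrum> %d channels x %d bins, resolution %.5f Hz (0-%.1f Hz)\n",
    nrow(x$amplitudes_uv), ncol(x$amplitudes_uv), x$freq_resolution_hz,
    max(x$frequencies_hz)
  ))
  invisible(x)
}

#' Locate the FFT bin of a stimulation frequency
#'
#' Maps a frequency to its spectrum bin index (0-based: bin k is at frequency
#' k x resolution, so bin 0 is DC). A hard error is raised when the frequency
#' does not align with the bin grid within the tolerance: silently snapping to
#' the nearest bin could misattribute a response to a neighbouring frequency.
#'
#' @param spectrum An [amplitude_spectrum][compute_spectrum], or a single
#'   number taken as the frequency resolution in Hz.
#' @param frequency_hz Target frequency.
#' @param tolerance Maximum allowed |frequency - bin centre|, as a fraction of
#'   the bin width (default 0.25).
#' @return Integer 0-based bin index.
#' @examples
#' target_bin(0.25, 5)     # bin 20
#' target_bin(1 / 60, 1.25) # bin 75
#' @export
target_bin <- function(spectrum, frequency_hz, tolerance = 0.25) {
  res <- if (is.numeric(spectrum)) spectrum else spectrum$freq_resolution_hz
  stopifnot(res > 0, frequency_hz >= 0)
  k <- round(frequency_hz / res)
  off <- abs(frequency_hz - k * res)
  if (off > tolerance * res + 1e-12) {
    stop(sprintf(
      "Frequency %g Hz is %.4g Hz from the nearest bin centre (resolution %g Hz); not bin-aligned.",
      frequency_hz, off, res
    ))
  }
  if (!is.numeric(spectrum) && k >= ncol(spectrum$amplitudes_uv)) {
    stop(sprintf("Frequency %g Hz is beyond the spectrum's Nyquist limit.", frequency_hz))
  }
  as.integer(k)
}

#' Neighbouring-bin set used as the local noise estimate
#'
#' The response statistics at a target bin are referenced to the surrounding
#' frequency bins: `n_per_side` bins on each side, skipping
#' `exclude_adjacent` bins immediately flanking the target (which may carry
#' spectral leakage from the response itself). The default 10 + 10 bins with
#' one excluded neighbour per side realises the conventional "20 surrounding
#' bins" noise estimate.
#'
#' @param spectrum An [amplitude_spectrum][compute_spectrum] (or the total
#'   number of bins as a single number).
#' @param target_bin 0-based target bin index.
#' @param n_per_side Neighbours kept on each side.
#' @param exclude_adjacent Bins skipped immediately next to the target, per side.
#' @return List with `target_bin`, 0-based `neighbor_bins`, `excluded_adjacent`.
#' @examples
#' neighborhood(500, 100, 10, 1)$neighbor_bins
#' @export
neighborhood <- function(spectrum, target_bin, n_per_side = 10L,
                         exclude_adjacent = 1L) {
  n_bins <- if (is.numeric(spectrum)) spectrum else ncol(spectrum$amplitudes_uv)
  stopifnot(n_per_side >= 1, exclude_adjacent >= 0)
  lo <- target_bin - exclude_adjacent - seq_len(n_per_side)
  hi <- target_bin + exclude_adjacent + seq_len(n_per_side)
  if (min(lo) < 0 || max(hi) > n_bins - 1L) {
    stop(sprintf(
      "Target bin %d is too close to the spectrum edge for %d neighbours per side.",
      target_bin, n_per_side
    ))
  }
  list(
    target_bin = as.integer(target_bin),
    neighbor_bins = as.integer(sort(c(lo, hi))),
    excluded_adjacent = as.integer(exclude_adjacent)
  )
}

#' Response statistics at a stimulation frequency bin
#'
#' Computes, for one channel and target frequency, the three statistics used
#' to quantify frequency-tagged responses against the local noise level of
#' the `n_per_side * 2` surrounding bins:
#'
#' * **SNR** - target amplitude divided by the mean neighbour amplitude;
#' * **baseline-subtracted amplitude** (µV) - target amplitude minus the mean
#'   neighbour amplitude (may be negative);
#' * **z** - baseline-subtracted amplitude divided by the neighbour SD
#'   (sample SD, n - 1 denominator).
#'
#' Degenerate neighbourhoods produce sentinels with a warning: a zero
#' neighbour mean gives `snr = Inf`, and a zero neighbour SD gives
#' `z = +/-Inf` (sign of the baseline-subtracted amplitude, `NaN` at 0).
#'
#' @param spectrum An [amplitude_spectrum][compute_spectrum].
#' @param channel Channel label or index.
#' @param frequency_hz Target frequency (must be bin-aligned).
#' @param n_per_side,exclude_adjacent Passed to [neighborhood()].
#' @param tolerance Passed to [target_bin()].
#' @return List of class `bin_stats`: `frequency_hz`, `amplitude_uv`, `snr`,
#'   `baseline_subtracted_uv`, `z`, `noise_mean_uv`, `noise_sd_uv`.
#' @export
bin_stats <- function(spectrum, channel, frequency_hz,
                      n_per_side = 10L, exclude_adjacent = 1L,
                      tolerance = 0.25) {
  k <- target_bin(spectrum, frequency_hz, tolerance)
  nb <- neighborhood(spectrum, k, n_per_side, exclude_adjacent)
  a <- spectrum$amplitudes_uv[channel, , drop = TRUE]
  a_t <- a[k + 1L]
  a_n <- a[nb$neighbor_bins + 1L]
  m <- mean(a_n)
  s <- stats::sd(a_n)
  diff <- a_t - m
  snr <- if (m > 0) a_t / m else {
    warning("Zero neighbourhood mean amplitude; SNR reported as Inf.")
    if (a_t > 0) Inf else NaN
  }
  z <- if (s > 0) diff / s else {
    warning("Zero neighbourhood amplitude SD; z reported as a signed-Inf sentinel.")
    if (diff == 0) NaN else sign(diff) * Inf
  }
  structure(
    list(
      frequency_hz = frequency_hz,
      amplitude_uv = unname(a_t),
      snr = unname(snr),
      baseline_subtracted_uv = unname(diff),
      z = unname(z),
      noise_mean_uv = unname(m),
      noise_sd_uv = unname(s)
    ),
    class = "bin_stats"
  )
}

#' @exportS3Method base::print
print.bin_stats <- function(x, ...) {
  cat(sprintf(
    "<bin_stats @ %g Hz> amplitude %.4g uV | SNR %.3g | baseline-subtracted %.4g uV | z %.3g\n",
    x$frequency_hz, x$amplitude_uv, x$snr, x$baseline_subtracted_uv, x$z
  ))
  invisible(x)
}

#' Spectrum as a long-format tibble
#'
#' @param spectrum An [amplitude_spectrum][compute_spectrum].
#' @param max_frequency_hz Optional upper frequency cut for export.
#' @return Tibble with columns subject, condition, channel, frequency_hz,
#'   amplitude_uv.
#' @export
spectrum_to_table <- function(spectrum, max_frequency_hz = NULL) {
  keep <- if (is.null(max_frequency_hz)) {
    seq_along(spectrum$frequencies_hz)
  } else {
    which(spectrum$frequencies_hz <= max_frequency_hz)
  }
  tibble::tibble(
    subject = spectrum$subject_id %||% NA_character_,
    condition = spectrum$condition %||% NA_character_,
    channel = rep(spectrum$channel_labels, each = length(keep)),
    frequency_hz = rep(spectrum$frequencies_hz[keep],
                       times = length(spectrum$channel_labels)),
    amplitude_uv = as.vector(t(spectrum$amplitudes_uv[, keep, drop = FALSE]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
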