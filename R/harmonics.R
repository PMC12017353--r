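#' Enumerate the harmonics that carry a frequency-tagged response
#'
#' Candidate harmonics are the ascending integer multiples of the
#' fundamental. Multiples that coincide with a multiple of
#' `exclude_multiples_of_hz` are dropped (with the reason recorded): in the
#' oddball design the fourth oddball harmonic (5 Hz) is simultaneously the
#' base-rate fundamental and carries the general visual response, not the
#' discrimination response, so the summation set for a 1.25 Hz oddball is
#' 1.25, 2.5, 3.75, 6.25 and 7.5 Hz. Coincidence is decided by exact rational
#' comparison of harmonic indices (is `k * fundamental` an integer multiple
#' of the excluded rate), never by floating-point equality of frequencies.
#'
#' @param fundamental_hz Fundamental stimulation frequency.
#' @param n_keep Number of harmonics retained after exclusion.
#' @param exclude_multiples_of_hz Optional rate whose multiples are excluded.
#' @return Object of class `harmonic_set`: `fundamental_hz`, `candidate_hz`,
#'   `excluded_hz`, `excluded_reason`, `retained_hz`.
#' @examples
#' enumerate_harmonics(1.25, 5, exclude_multiples_of_hz = 5)$retained_hz
#' enumerate_harmonics(4.61, 4)$retained_hz
#' @export
enumerate_harmonics <- function(fundamental_hz, n_keep,
                                exclude_multiples_of_hz = NULL) {
  stopifnot(fundamental_hz > 0, n_keep >= 1)
  k <- 1L
  retained <- numeric(0)
  excluded <- numeric(0)
  candidates <- numeric(0)
  while (length(retained) < n_keep) {
    f <- k * fundamental_hz
    candidates <- c(candidates, f)
    drop <- FALSE
    if (!is.null(exclude_multiples_of_hz)) {
      # rational test: k * fundamental / exclude integer within 1 part in 1e9
      ratio <- f / exclude_multiples_of_hz
      drop <- abs(ratio - round(ratio)) < 1e-9 && round(ratio) >= 1
    }
    if (drop) excluded <- c(excluded, f) else retained <- c(retained, f)
    k <- k + 1L
    if (k > 10000L) stop("Harmonic enumeration did not terminate.")
  }
  structure(
    list(
      fundamental_hz = fundamental_hz,
      candidate_hz = candidates,
      excluded_hz = excluded,
      excluded_reason = rep("coincides with excluded base rate",
                            length(excluded)),
      retained_hz = retained
    ),
    class = "harmonic_set"
  )
}

#' @exportS3Method base::print
print.harmonic_set <- function(x, ...) {
  cat(sprintf("<harmonic_set> fundamental %g Hz; retained: %s Hz%s\n",
              x$fundamental_hz, paste(x$retained_hz, collapse = ", "),
              if (length(x$excluded_hz)) {
                sprintf(" (excluded: %s Hz)",
                        paste(x$excluded_hz, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Select significant harmonics with the consecutive-failure rule
#'
#' Given a table of Z-scores for each candidate harmonic (rows, ascending
#' frequency) in every analysis cell (columns: e.g. each ROI x group x
#' content combination, computed on group-average spectra), harmonics are
#' retained as the ascending prefix that ends just before the first run of
#' `run_length` consecutive harmonics failing the threshold in at least one
#' cell, trimmed so that the prefix always ends on a significant harmonic.
#' This keeps an isolated sub-threshold harmonic flanked by significant
#' ones, matching the convention that the response "stops" only once two
#' consecutive harmonics fall below the one-sided significance cut-off.
#' `mode = "strict"` instead keeps only the harmonics that are themselves
#' above threshold in all cells (within that prefix).
#'
#' @param z_table Numeric matrix or data frame, harmonics x cells; a vector is
#'   treated as a single cell.
#' @param threshold Z threshold; the default `qnorm(0.95)` is the one-sided
#'   5% critical value (1.64 to two decimals).
#' @param run_length How many consecutive failures terminate the response.
#' @param mode `"prefix"` (default) or `"strict"`.
#' @return List: `retained` (count), `keep` (logical per harmonic),
#'   `pass` (logical per harmonic: significant in every cell), `threshold`.
#' @examples
#' select_significant(c(2.1, 1.9, 1.7, 1.1, 0.9, 0.5))$retained  # 3
#' @export
select_significant <- function(z_table, threshold = stats::qnorm(0.95),
                               run_length = 2L,
                               mode = c("prefix", "strict")) {
  mode <- match.arg(mode)
  if (is.null(dim(z_table))) z_table <- matrix(z_table, ncol = 1)
  z_table <- as.matrix(z_table)
  if (nrow(z_table) == 0) stop("Empty Z-score table.")
  stopifnot(run_length >= 1)
  pass <- apply(z_table > threshold, 1, all)
  n <- length(pass)
  cut <- n
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (pass[i]) 0L else run + 1L
    if (run >= run_length) {
      cut <- i - run
      break
    }
  }
  # the retained set always ends on a significant harmonic: trailing
  # failures too short to form a terminating run are trimmed
  while (cut > 0L && !pass[cut]) cut <- cut - 1L
  keep <- seq_len(n) <= cut
  if (mode == "strict") keep <- keep & pass
  list(retained = sum(keep), keep = keep, pass = pass, threshold = threshold)
}

#' Average amplitude spectra across subjects
#'
#' Element-wise mean of the amplitude matrices (spectra must share the same
#' bin grid and channel set). Used to build the group-average spectra on
#' which harmonic significance is assessed.
#'
#' @param spectra List of [amplitude_spectrum][compute_spectrum] objects.
#' @return An `amplitude_spectrum` with the averaged amplitudes.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  ref <- spectra[[1]]
  for (sp in spectra[-1]) {
    if (!isTRUE(all.equal(sp$freq_resolution_hz, ref$freq_resolution_hz)) ||
        !identical(dim(sp$amplitudes_uv), dim(ref$amplitudes_uv))) {
      stop("Spectra to average must share bin grid and channel set.")
    }
  }
  out <- ref
  out$amplitudes_uv <- Reduce(`+`, lapply(spectra, `[[`, "amplitudes_uv")) /
    length(spectra)
  out$subject_id <- "group-average"
  out
}

#' Collapse a spectrum's channels to ROI averages
#'
#' @param spectrum An [amplitude_spectrum][compute_spectrum].
#' @param rois Named list of channel sets, as [roi_definitions()].
#' @return An `amplitude_spectrum` with one row per ROI.
#' @export
roi_spectrum <- function(spectrum, rois = roi_definitions()) {
  missing <- setdiff(unlist(rois), spectrum$channel_labels)
  if (length(missing)) {
    stop("Spectrum is missing ROI channels: ", paste(missing, collapse = ", "))
  }
  amp <- t(vapply(rois, function(chans) {
    colMeans(spectrum$amplitudes_uv[chans, , drop = FALSE])
  }, numeric(ncol(spectrum$amplitudes_uv))))
  out <- spectrum
  out$amplitudes_uv <- amp
  out$channel_labels <- names(rois)
  out
}

#' Z-scores of candidate harmonics on group-average ROI spectra
#'
#' Builds the harmonic x cell Z table consumed by [select_significant()].
#' Each cell is a named group of per-subject spectra (e.g. one per group x
#' content combination); spectra are averaged within the cell, collapsed to
#' ROI averages, and the Z-score of every candidate harmonic is computed per
#' ROI.
#'
#' @param cell_spectra Named list; each element a list of
#'   [amplitude_spectrum][compute_spectrum] objects for one cell.
#' @param harmonic_set A [harmonic_set][enumerate_harmonics].
#' @param rois Named list of ROI channel sets.
#' @param n_per_side,exclude_adjacent Neighbourhood parameters
#'   (see [bin_stats()]).
#' @return Matrix, harmonics x (cell x ROI) columns.
#' @export
harmonic_z_table <- function(cell_spectra, harmonic_set,
                             rois = roi_definitions(),
                             n_per_side = 10L, exclude_adjacent = 1L) {
  stopifnot(length(cell_spectra) >= 1)
  cols <- list()
  for (cell in names(cell_spectra)) {
    avg <- roi_spectrum(average_spectra(cell_spectra[[cell]]), rois)
    for (roi in names(rois)) {
      cols[[paste(cell, roi, sep = ".")]] <- vapply(
        harmonic_set$retained_hz,
        function(f) bin_stats(avg, roi, f, n_per_side, exclude_adjacent)$z,
        numeric(1)
      )
    }
  }
  do.call(cbind, cols)
}

#' Summed baseline-subtracted response over harmonics, per ROI
#'
#' For one subject's spectrum: the baseline-subtracted amplitude is computed
#' per channel at every retained harmonic, summed over harmonics, and then
#' averaged across the ROI's channels. (All three operations are linear, so
#' their order does not change the value; this fixed order makes per-channel
#' diagnostics reproducible.)
#'
#' @param spectrum An [amplitude_spectrum][compute_spectrum] for one subject
#'   and condition.
#' @param harmonic_set A [harmonic_set][enumerate_harmonics]; only
#'   `retained_hz[keep]` enter the sum.
#' @param roi ROI name (see [roi_definitions()]) or a character vector of
#'   channel labels.
#' @param keep Optional logical vector from [select_significant()] choosing
#'   which retained harmonics to sum; default all.
#' @param n_per_side,exclude_adjacent Neighbourhood parameters.
#' @return Object of class `harmonic_summary`: `subject`, `condition`, `roi`,
#'   `summed_baseline_subtracted_uv`, `harmonics_hz`, and `per_harmonic`
#'   (tibble: channel, frequency_hz, amplitude_uv, snr,
#'   baseline_subtracted_uv, z).
#' @export
summed_response <- function(spectrum, harmonic_set, roi, keep = NULL,
                            n_per_side = 10L, exclude_adjacent = 1L) {
  channels <- if (length(roi) == 1 && roi %in% names(roi_definitions())) {
    roi_definitions(roi)[[1]]
  } else roi
  roi_name <- if (length(roi) == 1) roi else paste(roi, collapse = "+")
  missing <- setdiff(channels, spectrum$channel_labels)
  if (length(missing)) {
    stop("Spectrum is missing channels: ", paste(missing, collapse = ", "))
  }
  freqs <- harmonic_set$retained_hz
  if (!is.null(keep)) {
    stopifnot(length(keep) == length(freqs))
    freqs <- freqs[keep]
  }
  per <- do.call(rbind, lapply(channels, function(ch) {
    do.call(rbind, lapply(freqs, function(f) {
      st <- bin_stats(spectrum, ch, f, n_per_side, exclude_adjacent)
      tibble::tibble(channel = ch, frequency_hz = f,
                     amplitude_uv = st$amplitude_uv, snr = st$snr,
                     baseline_subtracted_uv = st$baseline_subtracted_uv,
                     z = st$z)
    }))
  }))
  per_channel_sum <- tapply(per$baseline_subtracted_uv, per$channel, sum)
  structure(
    list(
      subject = spectrum$subject_id,
      condition = spectrum$condition,
      roi = roi_name,
      summed_baseline_subtracted_uv = mean(per_channel_sum),
      harmonics_hz = freqs,
      per_harmonic = per
    ),
    class = "harmonic_summary"
  )
}

#' @exportS3Method base::print
print.harmonic_summary <- function(x, ...) {
  cat(sprintf(
    "<harmonic_summary> %s / %s / %s: %.4g uV summed over %d harmonics (%s Hz)\n",
    x$subject, x$condition, x$roi, x$summed_baseline_subtracted_uv,
    length(x$harmonics_hz), paste(x$harmonics_hz, collapse = ", ")
  ))
  invisible(x)
}

#' Harmonic summaries for a batch of spectra as a tidy table
#'
#' @param spectra List of per-subject [amplitude_spectrum][compute_spectrum]
#'   objects.
#' @param harmonic_set A [harmonic_set][enumerate_harmonics].
#' @param rois Named list of ROI channel sets.
#' @param keep,n_per_side,exclude_adjacent Passed to [summed_response()].
#' @return Tibble: subject, condition, roi, summed_uv.
#' @export
harmonic_summary_table <- function(spectra, harmonic_set,
                                   rois = roi_definitions(), keep = NULL,
                                   n_per_side = 10L, exclude_adjacent = 1L) {
  rows <- lapply(spectra, function(sp) {
    do.call(rbind, lapply(names(rois), function(roi) {
      s <- summed_response(sp, harmonic_set, rois[[roi]], keep,
                           n_per_side, exclude_adjacent)
      tibble::tibble(subject = sp$subject_id %||% NA_character_,
                     condition = sp$condition %||% NA_character_,
                     roi = roi, summed_uv = s$summed_baseline_subtracted_uv)
    }))
  })
  dplyr::bind_rows(rows)
}
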