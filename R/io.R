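#' Read and write the pipeline's CSV formats
#'
#' Plain-CSV interchange for every artefact of the pipeline: EEG recordings
#' in long format (`subject, condition, channel, sample_index, uv`), fixation
#' tables, cohort covariates, harmonic summaries and gaze results. The long
#' EEG format is bulky but lossless and toolchain-neutral.
#'
#' @param rec An [eeg_recording][simulate_eeg].
#' @param path Output/input file path.
#' @return `write_*` return the path invisibly; `read_eeg_csv` returns an
#'   `eeg_recording`, the other readers a tibble.
#' @name fpvs_io
NULL

#' @rdname fpvs_io
#' @export
write_eeg_csv <- function(rec, path) {
  x <- rec$samples
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  n <- dim(x)[2]
  n_ep <- dim(x)[3]
  df <- do.call(rbind, lapply(seq_len(n_ep), function(e) {
    data.frame(
      subject = rec$subject_id,
      condition = rec$condition,
      epoch = e,
      channel = rep(rec$channel_labels, each = n),
      sample_index = rep(seq_len(n) - 1L, times = length(rec$channel_labels)),
      uv = as.vector(t(x[, , e]))
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fpvs_io
#' @param sampling_rate_hz Sampling rate of the stored recording (the long
#'   CSV format does not carry it).
#' @param paradigm Optional [oddball_paradigm()] / [multi_input_paradigm()]
#'   to re-attach.
#' @export
read_eeg_csv <- function(path, sampling_rate_hz, paradigm = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "channel", "sample_index", "uv")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("EEG CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(df$epoch)) df$epoch <- 1L
  channels <- unique(df$channel)
  epochs <- sort(unique(df$epoch))
  n <- nrow(df) / length(channels) / length(epochs)
  x <- array(NA_real_, dim = c(length(channels), n, length(epochs)),
             dimnames = list(channels, NULL, NULL))
  for (e in seq_along(epochs)) {
    for (ch in channels) {
      sel <- df[df$channel == ch & df$epoch == epochs[e], ]
      x[ch, sel$sample_index + 1L, e] <- sel$uv
    }
  }
  if (length(epochs) == 1L) {
    dim(x) <- dim(x)[1:2]
    dimnames(x) <- list(channels, NULL)
  }
  structure(
    list(samples = x, channel_labels = channels,
         sampling_rate_hz = sampling_rate_hz,
         duration_s = n / sampling_rate_hz, paradigm = paradigm,
         components = NULL, subject_id = df$subject[1],
         condition = df$condition[1]),
    class = "eeg_recording"
  )
}

#' @rdname fpvs_io
#' @param table A tibble/data frame to write.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname fpvs_io
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
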