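#' Stimulation paradigm descriptors
#'
#' A fast periodic visual stimulation (FPVS) paradigm is described by the
#' presentation rates that frequency-tag each stimulus stream. Two designs are
#' supported: the *oddball* design, in which neutral base images appear at
#' `base_rate_hz` and a deviant (negative) image replaces every
#' `oddball_cycle`-th image so that discrimination responses appear at
#' `base_rate_hz / oddball_cycle` and its harmonics; and the *multi-input*
#' design, in which two image streams are presented simultaneously at two
#' distinct rates (one negative, one neutral stream), so that the relative
#' tagged amplitudes index the neural salience of each stream.
#'
#' @param base_rate_hz Base presentation rate in Hz (default 5).
#' @param oddball_cycle Every how many base images a deviant appears
#'   (default 4, giving a 1.25 Hz oddball rate).
#' @param content `"social"` or `"nonsocial"` scene content.
#' @return An object of class `fpvs_paradigm`.
#' @examples
#' oddball_paradigm()
#' multi_input_paradigm()
#' @export
oddball_paradigm <- function(base_rate_hz = 5, oddball_cycle = 4L,
                             content = c("social", "nonsocial")) {
  content <- match.arg(content)
  stopifnot(base_rate_hz > 0)
  if (oddball_cycle < 2) {
    stop("`oddball_cycle` must be >= 2 (a deviant every image is no oddball).")
  }
  structure(
    list(
      paradigm_kind = "oddball",
      base_rate_hz = base_rate_hz,
      oddball_cycle = as.integer(oddball_cycle),
      oddball_rate_hz = base_rate_hz / oddball_cycle,
      content = content
    ),
    class = "fpvs_paradigm"
  )
}

#' @rdname oddball_paradigm
#' @param stream_rates_hz Named pair of presentation rates for the two
#'   simultaneous streams; names give the stream labels.
#' @param valence_assignment Mapping of stream label to valence
#'   (`"negative"`/`"neutral"`).
#' @param side_assignment Mapping of stream label to visual field
#'   (`"left"`/`"right"`).
#' @export
multi_input_paradigm <- function(stream_rates_hz = c(stream1 = 4.61, stream2 = 5),
                                 valence_assignment = c(stream1 = "negative",
                                                        stream2 = "neutral"),
                                 side_assignment = c(stream1 = "left",
                                                     stream2 = "right"),
                                 content = c("social", "nonsocial")) {
  content <- match.arg(content)
  stopifnot(length(stream_rates_hz) == 2, all(stream_rates_hz > 0))
  if (isTRUE(all.equal(stream_rates_hz[[1]], stream_rates_hz[[2]]))) {
    stop("The two stream rates must be distinct to tag the streams.")
  }
  if (is.null(names(stream_rates_hz))) {
    names(stream_rates_hz) <- c("stream1", "stream2")
  }
  stopifnot(
    setequal(names(valence_assignment), names(stream_rates_hz)),
    setequal(sort(unname(valence_assignment)), c("negative", "neutral"))
  )
  structure(
    list(
      paradigm_kind = "multi_input",
      stream_rates_hz = stream_rates_hz,
      valence_assignment = valence_assignment,
      side_assignment = side_assignment,
      content = content
    ),
    class = "fpvs_paradigm"
  )
}

#' @exportS3Method base::print
print.fpvs_paradigm <- function(x, ...) {
  if (x$paradigm_kind == "oddball") {
    cat(sprintf(
      "<fpvs_paradigm: oddball> base %g Hz, deviant every %d images (oddball %g Hz), %s content\n",
      x$base_rate_hz, x$oddball_cycle, x$oddball_rate_hz, x$content
    ))
  } else {
    cat(sprintf(
      "<fpvs_paradigm: multi-input> %s, %s content\n",
      paste(sprintf("%s @ %g Hz (%s, %s)", names(x$stream_rates_hz),
                    x$stream_rates_hz, x$valence_assignment[names(x$stream_rates_hz)],
                    x$side_assignment[names(x$stream_rates_hz)]),
            collapse = "; "),
      x$content
    ))
  }
  invisible(x)
}

#' Tagged frequencies of a paradigm
#'
#' Returns the fundamental frequencies that tag each response of interest:
#' for the oddball design the oddball rate and the base rate, for the
#' multi-input design the two stream rates.
#'
#' @param paradigm An [oddball_paradigm()] or [multi_input_paradigm()].
#' @return Named numeric vector of fundamentals in Hz.
#' @export
tagged_frequencies <- function(paradigm) {
  stopifnot(inherits(paradigm, "fpvs_paradigm"))
  if (paradigm$paradigm_kind == "oddball") {
    c(oddball = paradigm$oddball_rate_hz, base = paradigm$base_rate_hz)
  } else {
    paradigm$stream_rates_hz
  }
}

#' Occipito-temporal and medial-occipital regions of interest
#'
#' The electrode groupings over which frequency-tagged responses are
#' aggregated: left occipito-temporal (LOT: P7, P9, PO7), medial occipital
#' (MO: Iz, Oz, O1, O2) and right occipito-temporal (ROT: P8, P10, PO8).
#'
#' @param which Optional character vector restricting which ROIs to return.
#' @return Named list of character vectors of 10-20-system channel labels.
#' @examples
#' roi_definitions()
#' roi_definitions("MO")
#' @export
roi_definitions <- function(which = c("LOT", "MO", "ROT")) {
  rois <- list(
    LOT = c("P7", "P9", "PO7"),
    MO  = c("Iz", "Oz", "O1", "O2"),
    ROT = c("P8", "P10", "PO8")
  )
  which <- match.arg(which, names(rois), several.ok = TRUE)
  rois[which]
}

#' All channels required by the standard ROI montage
#' @return Character vector of channel labels.
#' @keywords internal
roi_channels <- function() unique(unlist(roi_definitions(), use.names = FALSE))
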