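#' Rectangular area of interest (AOI)
#'
#' An AOI is the rectangular screen region where one scene stream is
#' presented. The analysis uses two stimulus AOIs (the negative and the
#' neutral stream) plus an implicit "outside" AOI covering everything else.
#'
#' @param label AOI label, e.g. `"negative"` or `"neutral"`.
#' @param x_min,x_max,y_min,y_max Rectangle bounds in screen pixels.
#' @return Object of class `aoi_rect`.
#' @examples
#' aoi_rect("negative", 100, 500, 200, 600)
#' @export
aoi_rect <- function(label, x_min, x_max, y_min, y_max) {
  if (!(x_min < x_max && y_min < y_max)) {
    stop("AOI rectangle must satisfy x_min < x_max and y_min < y_max.")
  }
  structure(list(label = label, x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max),
            class = "aoi_rect")
}

#' Default side-by-side AOI pair
#'
#' Two congruent rectangles left and right of the screen centre, the layout
#' of the simultaneous-stream (multi-input) display.
#'
#' @param screen_px `c(width, height)` in pixels.
#' @param size_px `c(width, height)` of each stimulus rectangle.
#' @param gap_px Horizontal gap between the two rectangles.
#' @param left_label,right_label AOI labels for the left and right rectangle.
#' @return List of two [aoi_rect()] objects named by label.
#' @export
default_aois <- function(screen_px = c(1920, 1080), size_px = c(600, 450),
                         gap_px = 200, left_label = "negative",
                         right_label = "neutral") {
  cx <- screen_px[1] / 2
  cy <- screen_px[2] / 2
  left <- aoi_rect(left_label, cx - gap_px / 2 - size_px[1], cx - gap_px / 2,
                   cy - size_px[2] / 2, cy + size_px[2] / 2)
  right <- aoi_rect(right_label, cx + gap_px / 2, cx + gap_px / 2 + size_px[1],
                    cy - size_px[2] / 2, cy + size_px[2] / 2)
  stats::setNames(list(left, right), c(left_label, right_label))
}

#' Probability weights of a fixation over the AOIs
#'
#' Rather than assigning each fixation all-or-nothing to the AOI containing
#' its reported coordinates, the fixation is treated as an isotropic
#' bivariate Gaussian centred at the reported position with SD equal to the
#' subject's calibration validation error, so that poorer eye-tracking
#' calibration spreads a fixation's credit over nearby regions. The weight
#' given to each rectangle is the Gaussian probability mass over it (the
#' product of two one-dimensional normal interval masses); the "outside"
#' weight is the remainder. As the calibration error approaches zero the
#' weights converge to hard point-in-rectangle assignment.
#'
#' @param x_px,y_px Fixation coordinates in pixels.
#' @param calibration_error_px Subject's validation error (Gaussian SD, px).
#'   A value of 0 is accepted as the degenerate point-assignment limit.
#' @param aois List of [aoi_rect()] objects (the stimulus AOIs).
#' @param sd_multiplier Scale factor applied to the calibration error before
#'   it is used as the kernel SD.
#' @return Named numeric weights over the AOI labels plus `"outside"`,
#'   summing to 1.
#' @examples
#' aois <- default_aois()
#' fixation_weights(700, 540, 35, aois)
#' @export
fixation_weights <- function(x_px, y_px, calibration_error_px, aois,
                             sd_multiplier = 1) {
  if (!is.finite(x_px) || !is.finite(y_px)) {
    stop("Non-finite fixation coordinates.")
  }
  sd <- calibration_error_px * sd_multiplier
  w <- vapply(aois, function(a) {
    if (sd <= 0) {
      as.numeric(x_px >= a$x_min && x_px <= a$x_max &&
                 y_px >= a$y_min && y_px <= a$y_max)
    } else {
      (stats::pnorm(a$x_max, x_px, sd) - stats::pnorm(a$x_min, x_px, sd)) *
        (stats::pnorm(a$y_max, y_px, sd) - stats::pnorm(a$y_min, y_px, sd))
    }
  }, numeric(1))
  names(w) <- vapply(aois, `[[`, character(1), "label")
  c(w, outside = max(0, 1 - sum(w)))
}

#' Proportional looking times over AOIs
#'
#' The proportion of looking time attributed to each AOI is the
#' duration-weighted average of the per-fixation probability weights:
#' `proportion(A) = sum_i duration_i * weight_i(A) / sum_i duration_i`.
#' Fixations with non-finite coordinates are dropped (their count is
#' reported in the result).
#'
#' @param fixations Data frame with columns `x_px`, `y_px`, `duration_s` and
#'   `calibration_error_px` (constant per subject, or per row).
#' @param aois List of [aoi_rect()] objects.
#' @param sd_multiplier Passed to [fixation_weights()].
#' @return Object of class `gaze_result`: `proportions` (named, sums to 1),
#'   `total_looking_s`, `n_fixations`, `n_dropped`.
#' @examples
#' fx <- data.frame(x_px = c(700, 1200), y_px = 540,
#'                  duration_s = c(3, 1), calibration_error_px = 1e-6)
#' proportional_looking(fx, default_aois())$proportions
#' @export
proportional_looking <- function(fixations, aois, sd_multiplier = 1) {
  ok <- is.finite(fixations$x_px) & is.finite(fixations$y_px) &
    is.finite(fixations$duration_s)
  dropped <- sum(!ok)
  fixations <- fixations[ok, , drop = FALSE]
  if (nrow(fixations) == 0) stop("No valid fixations.")
  total <- sum(fixations$duration_s)
  if (total <= 0) stop("Total fixation duration is zero.")
  labels <- c(vapply(aois, `[[`, character(1), "label"), "outside")
  acc <- stats::setNames(numeric(length(labels)), labels)
  for (i in seq_len(nrow(fixations))) {
    w <- fixation_weights(fixations$x_px[i], fixations$y_px[i],
                          fixations$calibration_error_px[i], aois,
                          sd_multiplier)
    acc <- acc + fixations$duration_s[i] * w
  }
  structure(
    list(
      proportions = acc / total,
      total_looking_s = total,
      n_fixations = nrow(fixations),
      n_dropped = dropped
    ),
    class = "gaze_result"
  )
}

#' @exportS3Method base::print
print.gaze_result <- function(x, ...) {
  cat(sprintf("<gaze_result> %d fixations (%.1f s): %s\n",
              x$n_fixations, x$total_looking_s,
              paste(sprintf("%s %.3f", names(x$proportions), x$proportions),
                    collapse = ", ")))
  invisible(x)
}
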