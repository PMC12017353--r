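#' Simulate a fixation stream over two stimulus AOIs
#'
#' Draws a sequence of fixations for one subject and condition: each
#' fixation targets the negative AOI, the neutral AOI or elsewhere with the
#' supplied probabilities, lands within the targeted rectangle with the
#' centre bias characteristic of scene viewing (truncated Gaussian around
#' the rectangle centre, SD one sixth of the rectangle size, so essentially
#' no true fixation sits on the image border), and is then jittered by
#' isotropic Gaussian calibration noise with SD `calibration_error_px`,
#' emulating eye-tracker measurement error. Durations are gamma-distributed
#' around `mean_duration_s`. Realised dwell proportions therefore converge
#' to the configured probabilities as the fixation count grows, and the
#' scatter of recorded positions around true target points has SD equal to
#' the calibration error.
#'
#' @param cfg A [sim_config()] supplying `n_fixations` and the default
#'   calibration error and seed.
#' @param aois List of two [aoi_rect()] objects (see [default_aois()]).
#' @param dwell_probabilities Named probabilities over
#'   `c(names(aois), "outside")`; must sum to 1. Default from `cfg`, with
#'   names matched to the AOI labels by position.
#' @param subject_id,condition Identifiers (enter the derived seed).
#' @param calibration_error_px Override of the per-subject calibration error.
#' @param mean_duration_s Mean fixation duration.
#' @param screen_px Screen size, bounding the outside fixations.
#' @return Tibble of fixation records: `subject`, `condition`, `x_px`,
#'   `y_px`, `onset_s`, `duration_s`, `calibration_error_px`, `target`
#'   (ground-truth AOI label).
#' @examples
#' cfg <- sim_config(seed = 3)
#' fx <- simulate_fixations(cfg, default_aois())
#' table(fx$target)
#' @export
simulate_fixations <- function(cfg, aois = default_aois(),
                               dwell_probabilities = NULL,
                               subject_id = "s01", condition = "social",
                               calibration_error_px = NULL,
                               mean_duration_s = 0.3,
                               screen_px = c(1920, 1080)) {
  stopifnot(inherits(cfg, "sim_config"), length(aois) == 2)
  labels <- vapply(aois, `[[`, character(1), "label")
  if (is.null(dwell_probabilities)) {
    dwell_probabilities <- stats::setNames(as.numeric(cfg$dwell_probabilities),
                                           c(labels, "outside"))
  }
  if (abs(sum(dwell_probabilities) - 1) > 1e-9) {
    stop("`dwell_probabilities` must sum to 1.")
  }
  if (any(dwell_probabilities < 0)) stop("Dwell probabilities must be >= 0.")
  all_labels <- c(labels, "outside")
  stopifnot(setequal(names(dwell_probabilities), all_labels))
  calib <- calibration_error_px %||% cfg$calibration_error_px
  stopifnot(calib > 0)

  set.seed(derive_seed(cfg$seed, "fix", subject_id, condition))
  n <- cfg$n_fixations
  target <- sample(all_labels, n, replace = TRUE,
                   prob = dwell_probabilities[all_labels])
  xy <- t(vapply(target, function(tg) {
    if (tg == "outside") {
      sample_outside(aois, screen_px)
    } else {
      a <- aois[[which(labels == tg)]]
      c(rtrunc_center(a$x_min, a$x_max), rtrunc_center(a$y_min, a$y_max))
    }
  }, numeric(2)))
  xy <- xy + matrix(stats::rnorm(2 * n, 0, calib), ncol = 2)
  dur <- stats::rgamma(n, shape = 4, rate = 4 / mean_duration_s)
  tibble::tibble(
    subject = subject_id,
    condition = condition,
    x_px = xy[, 1],
    y_px = xy[, 2],
    onset_s = cumsum(c(0, dur[-n])),
    duration_s = dur,
    calibration_error_px = calib,
    target = target
  )
}

# centre-biased coordinate inside an interval: truncated Gaussian around the
# midpoint with SD = width / 6 (scene fixations cluster on image centres)
rtrunc_center <- function(lo, hi) {
  mid <- (lo + hi) / 2
  s <- (hi - lo) / 6
  for (i in 1:100) {
    x <- stats::rnorm(1, mid, s)
    if (x > lo && x < hi) return(x)
  }
  mid
}

# rejection-sample a point on screen outside both AOI rectangles
sample_outside <- function(aois, screen_px) {
  for (i in 1:1000) {
    p <- c(stats::runif(1, 0, screen_px[1]), stats::runif(1, 0, screen_px[2]))
    inside <- any(vapply(aois, function(a) {
      p[1] >= a$x_min && p[1] <= a$x_max && p[2] >= a$y_min && p[2] <= a$y_max
    }, logical(1)))
    if (!inside) return(p)
  }
  stop("Could not sample an outside-AOI point; AOIs cover the screen.")
}
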