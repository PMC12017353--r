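#' Simulate a cohort with the modelled effect structure
#'
#' Generates subject-level covariates and per-cell outcome tables whose true
#' means obey the configured effects, so that the cohort-level mixed models
#' can be validated against known ground truth:
#'
#' * **Covariates** - group (control / adversity), age (the adversity group
#'   is slightly older), sex (female-majority), continuous threat and neglect
#'   exposure scores (near zero in controls, gamma-distributed in the
#'   adversity group), a composite childhood-adversity score (the
#'   category-weighted mean of threat and neglect, 5:2, mirroring a
#'   seven-category victimisation questionnaire), and depression, anxiety and
#'   psychosis scores correlated with adversity exposure through a shared
#'   severity factor.
#' * **Oddball outcome** - one row per subject x content x ROI. The control
#'   group carries a social-minus-nonsocial content effect of
#'   `group_content_gap` within-subject SDs; in the adversity group the
#'   content effect is `threat_content_slope * z(threat) +
#'   neglect_content_slope * z(neglect)` (zero on average), yielding the
#'   group-by-content interaction and the threat-by-content modulation.
#'   Fixed mild ROI and ROI-by-content structure (right-lateralised social
#'   responses, medial-occipital dominance for non-social content) adds
#'   realism.
#' * **Multi-input neural outcome** - one row per subject x valence x
#'   content x rate. Valence (neutral minus negative) effect
#'   `valence_effect`, larger in the social context by
#'   `valence_content_interaction`, plus a per-subject latent
#'   valence-sensitivity factor of SD `neural_sens_sd`.
#' * **Gaze outcome** - proportional looking time per subject x valence x
#'   content x rate: neutral preference `gaze_valence_effect`, reduced by
#'   `adversity_valence_gaze_slope` per SD of adversity, plus a latent
#'   valence-sensitivity factor correlated `gaze_neural_loading` with the
#'   neural one (this induces the gaze-neural correlation).
#'
#' Every effect-size parameter set to zero removes that effect exactly, so
#' null configurations are obtained by zeroing the relevant parameters (see
#' [null_sim_config()]).
#'
#' @param cfg A [sim_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return List of class `fpvs_cohort` with tibbles `covariates`, `oddball`,
#'   `multiinput_neural`, `gaze`; outcome tibbles carry `y_true` (noise-free
#'   cell mean) and `y` (with within-subject noise).
#' @examples
#' sim <- simulate_cohort(sim_config(n_control = 4, n_adversity = 4, seed = 1))
#' head(sim$oddball)
#' @export
simulate_cohort <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_control < 2 || cfg$n_adversity < 2) stop("Group sizes must be >= 2.")
  set.seed(derive_seed(seed %||% cfg$seed, "cohort"))
  n <- cfg$n_control + cfg$n_adversity
  w <- cfg$within_sd

  subject <- sprintf("s%03d", seq_len(n))
  group <- rep(c("control", "adversity"), c(cfg$n_control, cfg$n_adversity))
  age <- round(ifelse(group == "control",
                      stats::rnorm(n, 23.5, 2.5), stats::rnorm(n, 26, 4)), 1)
  age <- pmax(age, 18)
  sex <- ifelse(stats::runif(n) < cfg$female_ratio, "female", "male")
  threat <- ifelse(group == "control",
                   abs(stats::rnorm(n, 0, 0.08)),
                   stats::rgamma(n, shape = 2, scale = 0.5))
  neglect <- ifelse(group == "control",
                    abs(stats::rnorm(n, 0, 0.1)),
                    stats::rgamma(n, shape = 2, scale = 0.4))
  adversity <- (5 * threat + 2 * neglect) / 7
  z_adv_all <- as.numeric(scale(adversity))
  severity <- 0.6 * z_adv_all + stats::rnorm(n, 0, sqrt(1 - 0.36))
  mk_score <- function(mean, sd, floor = 0) {
    pmax(floor, round(mean + sd * (0.7 * severity +
                                     stats::rnorm(n, 0, sqrt(1 - 0.49))), 1))
  }
  depression <- mk_score(12, 8)
  anxiety <- mk_score(42, 10)
  psychosis <- mk_score(4, 3)

  # z-scores of exposure within the adversity group (slopes are defined per
  # adversity-group SD; controls sit below that group's mean)
  z_within <- function(x) {
    m <- mean(x[group == "adversity"])
    s <- stats::sd(x[group == "adversity"])
    (x - m) / s
  }
  z_thr <- z_within(threat)
  z_neg <- z_within(neglect)
  z_ca <- z_within(adversity)

  covariates <- tibble::tibble(
    subject = subject, group = group, age = age, sex = sex,
    adversity = adversity, threat = threat, neglect = neglect,
    depression = depression, anxiety = anxiety, psychosis = psychosis
  )

  ## oddball outcome -------------------------------------------------------
  content_eff <- w * ifelse(
    group == "control",
    cfg$group_content_gap,
    cfg$threat_content_slope * z_thr + cfg$neglect_content_slope * z_neg
  )
  roi_eff <- c(LOT = -0.15, MO = 0.15, ROT = 0) * w * cfg$roi_effect_scale
  roi_content_eff <- c(LOT = 0.1, MO = -0.3, ROT = 0.2) * w *
    cfg$roi_effect_scale
  b_odd <- stats::rnorm(n, 0, cfg$between_sd)
  oddball <- tidyr::expand_grid(
    subject = subject,
    content = c("social", "nonsocial"),
    roi = c("LOT", "MO", "ROT")
  )
  i <- match(oddball$subject, subject)
  code_c <- ifelse(oddball$content == "social", 0.5, -0.5)
  oddball$y_true <- cfg$cohort_baseline_uv + b_odd[i] +
    roi_eff[oddball$roi] + code_c * (content_eff[i] +
                                       roi_content_eff[oddball$roi])
  oddball$y <- oddball$y_true + stats::rnorm(nrow(oddball), 0, w)

  ## latent valence sensitivity (shared between neural salience and gaze) --
  u1 <- stats::rnorm(n)
  u2 <- stats::rnorm(n)
  rho <- cfg$gaze_neural_loading
  sens_neural <- w * cfg$neural_sens_sd * u1
  sens_gaze <- cfg$gaze_sens_sd * (rho * u1 + sqrt(max(0, 1 - rho^2)) * u2)

  ## multi-input neural salience -------------------------------------------
  b_mi <- stats::rnorm(n, 0, cfg$between_sd)
  multiinput <- tidyr::expand_grid(
    subject = subject,
    valence = c("negative", "neutral"),
    content = c("social", "nonsocial"),
    rate_hz = c(4.61, 5)
  )
  i <- match(multiinput$subject, subject)
  code_v <- ifelse(multiinput$valence == "neutral", 0.5, -0.5)
  code_c <- ifelse(multiinput$content == "social", 0.5, -0.5)
  valence_eff <- w * (cfg$valence_effect +
                        cfg$valence_content_interaction * code_c) +
    sens_neural[i]
  multiinput$y_true <- cfg$cohort_baseline_uv + b_mi[i] + code_v * valence_eff
  multiinput$y <- multiinput$y_true + stats::rnorm(nrow(multiinput), 0, w)

  ## gaze proportions -------------------------------------------------------
  gaze <- multiinput[c("subject", "valence", "content", "rate_hz")]
  i <- match(gaze$subject, subject)
  code_v <- ifelse(gaze$valence == "neutral", 0.5, -0.5)
  gaze_valence_eff <- cfg$gaze_valence_effect -
    cfg$adversity_valence_gaze_slope * z_ca[i] + sens_gaze[i]
  gaze$y_true <- cfg$gaze_baseline + code_v * gaze_valence_eff
  gaze$y <- gaze$y_true + stats::rnorm(nrow(gaze), 0, cfg$gaze_within_sd)

  structure(
    list(covariates = covariates, oddball = oddball,
         multiinput_neural = multiinput, gaze = gaze, config = cfg),
    class = "fpvs_cohort"
  )
}

#' @exportS3Method base::print
print.fpvs_cohort <- function(x, ...) {
  cat(sprintf(
    "<fpvs_cohort> %d control + %d adversity subjects; %d oddball, %d neural, %d gaze data points\n",
    sum(x$covariates$group == "control"),
    sum(x$covariates$group == "adversity"),
    nrow(x$oddball), nrow(x$multiinput_neural), nrow(x$gaze)
  ))
  invisible(x)
}

#' Null variant of a simulation configuration
#'
#' Returns `cfg` with every systematic effect removed: group/content,
#' threat/neglect, valence (neural and gaze), the adversity gaze slope and
#' the latent valence-sensitivity factors are all set to zero, so that the
#' generated outcomes are exchangeable across conditions. Used for type-I
#' error calibration of the model pipeline.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_config` with zeroed effects.
#' @export
null_sim_config <- function(cfg) {
  cfg$group_content_gap <- 0
  cfg$roi_effect_scale <- 0
  cfg$threat_content_slope <- 0
  cfg$neglect_content_slope <- 0
  cfg$valence_effect <- 0
  cfg$valence_content_interaction <- 0
  cfg$neural_sens_sd <- 0
  cfg$gaze_valence_effect <- 0
  cfg$adversity_valence_gaze_slope <- 0
  cfg$gaze_sens_sd <- 0
  cfg
}
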