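#' Analysis configuration for a full pipeline run
#'
#' Bundles every tunable of the simulate - quantify - gaze - fit pipeline:
#' the synthetic-data configuration, the spectral neighbourhood, the
#' harmonic-selection rule, and the outlier-screening settings. The
#' configuration validates eagerly so that a misconfigured run fails before
#' any computation.
#'
#' @param sim A [sim_config()].
#' @param n_per_side,exclude_adjacent Spectral neighbourhood (see
#'   [neighborhood()]).
#' @param tolerance Bin-alignment tolerance, fraction of bin width.
#' @param oddball_n_keep Oddball harmonics to sum (after base-rate
#'   exclusion).
#' @param stream_n_keep Harmonics per multi-input stream.
#' @param z_threshold Harmonic-significance threshold; default the one-sided
#'   5% normal critical value.
#' @param run_length Consecutive failures that terminate the harmonic
#'   prefix (see [select_significant()]).
#' @param selection_mode `"prefix"` or `"strict"` harmonic selection.
#' @param mad_scale,mad_threshold Outlier screening (see [mad_outliers()]).
#' @param alpha Significance level used when reporting post-hoc contrasts.
#' @return Object of class `analysis_config`.
#' @examples
#' config <- analysis_config(sim_config(seed = 1))
#' @export
analysis_config <- function(sim = sim_config(),
                            n_per_side = 10L, exclude_adjacent = 1L,
                            tolerance = 0.25,
                            oddball_n_keep = 5L, stream_n_keep = 4L,
                            z_threshold = stats::qnorm(0.95),
                            run_length = 2L,
                            selection_mode = c("prefix", "strict"),
                            mad_scale = 1.4826, mad_threshold = 3,
                            alpha = 0.05) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(inherits(sim, "sim_config"), n_per_side >= 1,
            exclude_adjacent >= 0, tolerance > 0, tolerance <= 0.5,
            oddball_n_keep >= 1, stream_n_keep >= 1, z_threshold > 0,
            run_length >= 1, mad_scale > 0, mad_threshold > 0,
            alpha > 0, alpha < 1)
  # every ROI channel must exist in the simulated layout
  missing <- setdiff(roi_channels(), sim$channels)
  if (length(missing)) {
    stop("Layout is missing ROI channels: ", paste(missing, collapse = ", "))
  }
  structure(
    list(sim = sim, n_per_side = as.integer(n_per_side),
         exclude_adjacent = as.integer(exclude_adjacent),
         tolerance = tolerance,
         oddball_n_keep = as.integer(oddball_n_keep),
         stream_n_keep = as.integer(stream_n_keep),
         z_threshold = z_threshold, run_length = as.integer(run_length),
         selection_mode = selection_mode,
         mad_scale = mad_scale, mad_threshold = mad_threshold,
         alpha = alpha),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' The YAML file may contain a `sim:` section (arguments of [sim_config()])
#' and top-level entries for the remaining [analysis_config()] arguments.
#' Unknown keys are an error, so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `sim: seed:`.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  unknown <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(unknown)) {
    stop("Unknown sim config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) sim_args$seed <- seed
  raw$sim <- NULL
  unknown <- setdiff(names(raw), names(formals(analysis_config)))
  if (length(unknown)) {
    stop("Unknown analysis config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, c(list(sim = do.call(sim_config, sim_args)), raw))
}

#' Run the oddball frequency-tagging analysis end to end
#'
#' Simulates the cohort and one EEG recording per subject and content
#' condition (with the cohort's true per-ROI summed responses injected as
#' the oddball signal), computes amplitude spectra, assesses harmonic
#' significance on group-average ROI spectra (all ROIs, both groups, both
#' contents must exceed the Z threshold, with the two-consecutive-failure
#' stopping rule), sums baseline-subtracted amplitudes over the retained
#' harmonics per ROI, screens outliers per content x ROI cell, fits
#' Models 1-3 and computes Tukey-corrected post-hoc contrasts for the
#' group-by-content interaction. All randomness derives from the
#' configuration seed, so a rerun with the same configuration reproduces
#' every output byte for byte.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, harmonic summaries, model
#'   effect tables, contrasts and a JSON report are written there.
#' @return List of class `fpvs_run`: `cohort`, `summaries` (measured
#'   harmonic-summary table), `harmonics` (retained set and selection),
#'   `models` (list of [fit_lmm()] results), `contrasts`, `outliers`,
#'   `config`.
#' @export
run_oddball <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config$sim
  sim <- simulate_cohort(cfg)
  resolution <- 1 / cfg$duration_s

  odd_set <- enumerate_harmonics(
    snap_frequency(oddball_paradigm()$oddball_rate_hz, resolution),
    n_keep = config$oddball_n_keep, exclude_multiples_of_hz = 5
  )

  spectra <- list()
  for (s in sim$covariates$subject) {
    for (content in c("social", "nonsocial")) {
      truth <- sim$oddball[sim$oddball$subject == s &
                             sim$oddball$content == content, ]
      totals <- stats::setNames(truth$y_true, truth$roi)
      rec <- simulate_eeg(oddball_paradigm(content = content), cfg,
                          subject_id = s, condition = content,
                          oddball_total_uv = totals)
      spectra[[paste(s, content, sep = ".")]] <- compute_spectrum(rec)
    }
  }

  # harmonic significance on group-average ROI spectra, per group x content
  cells <- split(
    names(spectra),
    interaction(
      sim$covariates$group[match(sub("\\..*$", "", names(spectra)),
                                 sim$covariates$subject)],
      sub("^.*\\.", "", names(spectra)), drop = TRUE
    )
  )
  z_table <- harmonic_z_table(
    lapply(cells, function(idx) spectra[idx]), odd_set,
    n_per_side = config$n_per_side, exclude_adjacent = config$exclude_adjacent
  )
  selection <- select_significant(z_table, config$z_threshold,
                                  config$run_length, config$selection_mode)

  summaries <- harmonic_summary_table(
    spectra, odd_set, keep = selection$keep,
    n_per_side = config$n_per_side, exclude_adjacent = config$exclude_adjacent
  )
  names(summaries)[names(summaries) == "condition"] <- "content"
  names(summaries)[names(summaries) == "summed_uv"] <- "y"

  sim_measured <- list(covariates = sim$covariates, oddball = summaries)
  models <- list()
  tables <- list()
  for (m in 1:3) {
    tables[[m]] <- build_model_table(sim_measured, "oddball", model = m,
                                     screen = TRUE,
                                     scale_constant = config$mad_scale,
                                     threshold = config$mad_threshold)
    models[[paste0("model_", m)]] <- fit_lmm(model_spec(m, "oddball"),
                                             tables[[m]])
  }
  contrasts <- tukey_contrasts(models$model_1, ~ content | group)
  outliers <- lapply(tables, attr, "n_removed")

  run <- structure(
    list(cohort = sim, summaries = summaries,
         harmonics = list(set = odd_set, selection = selection,
                          z_table = z_table),
         models = models, contrasts = contrasts,
         outliers = outliers, config = config),
    class = "fpvs_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir, "oddball")
  run
}

#' Run the multi-input paradigm analysis end to end
#'
#' Simulates, for every subject and content, the two counterbalanced
#' rate-to-valence assignments of the simultaneous-stream display (negative
#' at 4.61 Hz / neutral at 5 Hz, and vice versa) with the cohort's true
#' salience amplitudes injected, quantifies each stream's summed response at
#' the medial-occipital ROI over its retained harmonics, simulates fixation
#' streams whose dwell probabilities follow the cohort's true gaze
#' proportions and recovers proportional looking times by probability
#' weighting, fits Models 1-3 for both outcomes, and correlates the
#' subject-level negative-minus-neutral difference scores of gaze and neural
#' salience per content context.
#'
#' @inheritParams run_oddball
#' @return List of class `fpvs_run`: `cohort`, `neural` and `gaze` measured
#'   tables, `harmonics` (per stream rate), `models` (per outcome),
#'   `correlation`, `config`.
#' @export
run_multiinput <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config$sim
  sim <- simulate_cohort(cfg)
  resolution <- 1 / cfg$duration_s
  rates <- c(4.61, 5)
  snapped <- vapply(rates, snap_frequency, numeric(1),
                    resolution_hz = resolution)
  sets <- lapply(snapped, enumerate_harmonics, n_keep = config$stream_n_keep)
  names(sets) <- as.character(rates)

  neural_rows <- list()
  spectra_by_cell <- list()
  for (s in sim$covariates$subject) {
    group <- sim$covariates$group[sim$covariates$subject == s]
    for (content in c("social", "nonsocial")) {
      truth <- sim$multiinput_neural[
        sim$multiinput_neural$subject == s &
          sim$multiinput_neural$content == content, ]
      for (neg_rate in rates) {
        neu_rate <- setdiff(rates, neg_rate)
        paradigm <- multi_input_paradigm(
          stream_rates_hz = c(stream1 = neg_rate, stream2 = neu_rate),
          content = content
        )
        cond <- sprintf("%s.neg%g", content, neg_rate)
        rec <- simulate_eeg(
          paradigm, cfg, subject_id = s, condition = cond,
          stream_total_uv = list(
            stream1 = truth$y_true[truth$valence == "negative" &
                                     truth$rate_hz == neg_rate],
            stream2 = truth$y_true[truth$valence == "neutral" &
                                     truth$rate_hz == neu_rate]
          )
        )
        sp <- compute_spectrum(rec)
        cell <- paste(group, content, sep = ".")
        spectra_by_cell[[cell]] <- c(spectra_by_cell[[cell]], list(sp))
        for (valence in c("negative", "neutral")) {
          rate <- if (valence == "negative") neg_rate else neu_rate
          resp <- summed_response(sp, sets[[as.character(rate)]], "MO",
                                  n_per_side = config$n_per_side,
                                  exclude_adjacent = config$exclude_adjacent)
          neural_rows[[length(neural_rows) + 1L]] <- tibble::tibble(
            subject = s, valence = valence, content = content,
            rate_hz = rate, y = resp$summed_baseline_subtracted_uv
          )
        }
      }
    }
  }
  neural <- dplyr::bind_rows(neural_rows)

  selections <- lapply(names(sets), function(rate) {
    z <- harmonic_z_table(spectra_by_cell, sets[[rate]],
                          rois = roi_definitions("MO"),
                          n_per_side = config$n_per_side,
                          exclude_adjacent = config$exclude_adjacent)
    select_significant(z, config$z_threshold, config$run_length,
                       config$selection_mode)
  })
  names(selections) <- names(sets)

  ## gaze stage -------------------------------------------------------------
  aois_by_side <- list(
    neg_left = default_aois(left_label = "negative", right_label = "neutral"),
    neg_right = default_aois(left_label = "neutral", right_label = "negative")
  )
  gaze_rows <- list()
  for (s in sim$covariates$subject) {
    calib <- NULL
    for (content in c("social", "nonsocial")) {
      truth <- sim$gaze[sim$gaze$subject == s & sim$gaze$content == content, ]
      for (i in seq_along(rates)) {
        neg_rate <- rates[i]
        neu_rate <- setdiff(rates, neg_rate)
        side <- names(aois_by_side)[i]  # counterbalance side with rate
        aois <- aois_by_side[[side]]
        p_neg <- truth$y_true[truth$valence == "negative" &
                                truth$rate_hz == neg_rate]
        p_neu <- truth$y_true[truth$valence == "neutral" &
                                truth$rate_hz == neu_rate]
        p_neg <- min(max(p_neg, 0), 1)
        p_neu <- min(max(p_neu, 0), 1 - p_neg)
        probs <- c(negative = p_neg, neutral = p_neu,
                   outside = 1 - p_neg - p_neu)
        fx <- simulate_fixations(cfg, aois, dwell_probabilities = probs,
                                 subject_id = s,
                                 condition = sprintf("%s.%s", content, side))
        gz <- proportional_looking(fx, aois)
        for (valence in c("negative", "neutral")) {
          rate <- if (valence == "negative") neg_rate else neu_rate
          gaze_rows[[length(gaze_rows) + 1L]] <- tibble::tibble(
            subject = s, valence = valence, content = content,
            rate_hz = rate, y = unname(gz$proportions[valence])
          )
        }
      }
    }
  }
  gaze <- dplyr::bind_rows(gaze_rows)

  sim_measured <- list(covariates = sim$covariates,
                       multiinput_neural = neural, gaze = gaze)
  models <- list()
  for (outcome in c("multiinput_neural", "multiinput_gaze")) {
    for (m in 1:3) {
      tbl <- build_model_table(sim_measured, outcome, model = m,
                               screen = TRUE,
                               scale_constant = config$mad_scale,
                               threshold = config$mad_threshold)
      models[[paste(outcome, m, sep = "_")]] <-
        fit_lmm(model_spec(m, outcome), tbl)
    }
  }
  correlation <- gaze_neural_correlation(gaze, neural)

  run <- structure(
    list(cohort = sim, neural = neural, gaze = gaze,
         harmonics = list(sets = sets, selections = selections),
         models = models, correlation = correlation, config = config),
    class = "fpvs_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir, "multiinput")
  run
}

#' @exportS3Method base::print
print.fpvs_run <- function(x, ...) {
  kind <- if (!is.null(x$summaries)) "oddball" else "multi-input"
  cat(sprintf("<fpvs_run: %s> %d subjects; models: %s\n", kind,
              nrow(x$cohort$covariates), paste(names(x$models),
                                               collapse = ", ")))
  invisible(x)
}

# write the tables and a JSON report of a pipeline run
write_run <- function(run, out_dir, prefix) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(name) file.path(out_dir, paste0(prefix, "_", name))
  write_table_csv(run$cohort$covariates, pth("cohort.csv"))
  if (!is.null(run$summaries)) {
    write_table_csv(run$summaries, pth("summaries.csv"))
  }
  if (!is.null(run$neural)) write_table_csv(run$neural, pth("neural.csv"))
  if (!is.null(run$gaze)) write_table_csv(run$gaze, pth("gaze.csv"))
  effects <- dplyr::bind_rows(lapply(names(run$models), function(nm) {
    dplyr::mutate(run$models[[nm]]$effects, model = nm, .before = 1)
  }))
  write_table_csv(effects, pth("effects.csv"))
  report <- list(
    package_version = as.character(utils::packageVersion("fpvstag")),
    config = config_as_list(run$config),
    effects = effects,
    correlation = run$correlation,
    contrasts = run$contrasts
  )
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out
}
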