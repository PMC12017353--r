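#' Median-absolute-deviation outlier screening
#'
#' Flags values whose robust z-score exceeds a threshold:
#' `|x - median(x)| / (scale_constant * mad_raw)` with `mad_raw` the raw
#' median absolute deviation. The default scale constant 1.4826 makes the
#' denominator a consistent estimate of the SD under normality; the default
#' threshold of 3 robust SDs is conventional for screening before modelling.
#' A zero MAD (more than half the values identical) yields no flags and a
#' warning rather than flagging every non-median value.
#'
#' @param values Numeric vector (length >= 3).
#' @param scale_constant Consistency constant applied to the raw MAD.
#' @param threshold Robust z-score cut-off.
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @examples
#' mad_outliers(c(1, 2, 3, 100))
#' @export
mad_outliers <- function(values, scale_constant = 1.4826, threshold = 3) {
  if (length(values) < 3) stop("Need at least 3 values for MAD screening.")
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  if (mad_raw == 0) {
    warning("MAD is zero; no outliers flagged.")
    return(rep(FALSE, length(values)))
  }
  abs(values - med) / (scale_constant * mad_raw) > threshold
}

#' Remove MAD outliers per analysis cell
#'
#' Applies [mad_outliers()] within each cell defined by the grouping columns
#' (e.g. ROI x condition for the oddball outcome, valence x content x rate
#' for the multi-input outcomes) and drops flagged rows, returning the
#' screened table with the removal log attached.
#'
#' @param table Data frame with the outcome in `value_col`.
#' @param cells Character vector of grouping column names.
#' @param value_col Outcome column name.
#' @param scale_constant,threshold Passed to [mad_outliers()].
#' @return The screened table; attribute `outlier_log` holds a tibble with
#'   per-cell flagged counts, and attribute `n_removed` the total.
#' @export
screen_outliers <- function(table, cells, value_col = "y",
                            scale_constant = 1.4826, threshold = 3) {
  idx <- interaction(table[cells], drop = TRUE)
  flags <- rep(FALSE, nrow(table))
  for (cell in levels(idx)) {
    sel <- which(idx == cell)
    if (length(sel) >= 3) {
      flags[sel] <- suppressWarnings(
        mad_outliers(table[[value_col]][sel], scale_constant, threshold)
      )
    }
  }
  log <- stats::aggregate(flags, by = list(cell = idx), FUN = sum)
  names(log)[2] <- "n_flagged"
  out <- table[!flags, , drop = FALSE]
  attr(out, "outlier_log") <- tibble::as_tibble(log)
  attr(out, "n_removed") <- sum(flags)
  out
}

#' Standardize to mean 0, SD 1
#'
#' @param values Numeric vector with positive SD (sample SD, n-1 denominator).
#' @return Z-scored values.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("Cannot standardize: SD is zero.")
  (values - mean(values)) / s
}

#' Specification of one of the three cohort-level mixed models
#'
#' Model 1 contrasts the two groups; Models 2 and 3 are fitted within the
#' adversity group only, entering childhood adversity (Model 2) or its
#' threat and neglect dimensions (Model 3) together with the symptom scores
#' as standardized continuous predictors. For the oddball outcome the
#' within-subject factors are Content (and ROI in Model 1); for the
#' multi-input outcomes they are Valence and Content.
#'
#' @param model 1, 2 or 3.
#' @param outcome `"oddball"`, `"multiinput_neural"` or `"multiinput_gaze"`.
#' @return Object of class `model_spec` with the model formula.
#' @examples
#' model_spec(1, "oddball")$formula
#' @export
model_spec <- function(model, outcome = c("oddball", "multiinput_neural",
                                          "multiinput_gaze")) {
  outcome <- match.arg(outcome)
  stopifnot(model %in% 1:3)
  oddball <- outcome == "oddball"
  fixed <- switch(as.character(model),
    "1" = if (oddball) "age + sex + group * content * roi"
          else "age + sex + group * valence * content",
    "2" = if (oddball) {
      "age + sex + adversity * content + depression * content + anxiety * content + psychosis * content"
    } else {
      "age + sex + adversity * valence * content + depression * valence * content + anxiety * valence * content + psychosis * valence * content"
    },
    "3" = if (oddball) {
      "age + sex + threat * content + neglect * content + depression * content + anxiety * content + psychosis * content"
    } else {
      "age + sex + threat * valence * content + neglect * valence * content + depression * valence * content + anxiety * valence * content + psychosis * valence * content"
    }
  )
  structure(
    list(model = as.integer(model), outcome = outcome,
         formula = stats::as.formula(paste("y ~", fixed, "+ (1 | subject)")),
         group_scope = if (model == 1) "both" else "adversity"),
    class = "model_spec"
  )
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> Model %d, %s outcome (%s):\n  ", x$model,
              x$outcome, if (x$group_scope == "both") "both groups"
              else "adversity group only"))
  print(x$formula)
  invisible(x)
}

#' Assemble the modelling table for one outcome
#'
#' Joins the cohort covariates to an outcome table, restricts to the
#' adversity group when the model demands it, standardizes the continuous
#' adversity and symptom measures (M = 0, SD = 1, after any restriction),
#' and codes all factors with sum-to-zero contrasts so that the type-III
#' F tests are contrast-invariant.
#'
#' @param sim A [simulate_cohort()] result, or a list with `covariates` and
#'   the outcome tibbles.
#' @param outcome Which outcome table to model.
#' @param model Model number (1-3); Models 2-3 restrict to the adversity
#'   group before standardization.
#' @param screen Apply per-cell MAD outlier screening before returning.
#' @param scale_constant,threshold MAD screening parameters.
#' @return Tibble ready for [fit_lmm()]; attributes `outlier_log` /
#'   `n_removed` when screening was applied.
#' @export
build_model_table <- function(sim, outcome = c("oddball", "multiinput_neural",
                                               "multiinput_gaze"),
                              model = 1, screen = FALSE,
                              scale_constant = 1.4826, threshold = 3) {
  outcome <- match.arg(outcome)
  src <- if (outcome == "multiinput_gaze") "gaze" else outcome
  tbl <- dplyr::inner_join(sim[[src]], sim$covariates, by = "subject")
  if (model >= 2) {
    tbl <- tbl[tbl$group == "adversity", , drop = FALSE]
  }
  for (col in c("adversity", "threat", "neglect", "depression", "anxiety",
                "psychosis")) {
    tbl[[col]] <- standardize(tbl[[col]])
  }
  tbl$subject <- factor(tbl$subject)
  for (col in intersect(c("group", "sex", "content", "roi", "valence"),
                        names(tbl))) {
    tbl[[col]] <- factor(tbl[[col]])
    if (nlevels(tbl[[col]]) >= 2) {
      stats::contrasts(tbl[[col]]) <- stats::contr.sum(nlevels(tbl[[col]]))
    }
  }
  if (screen) {
    cells <- if (outcome == "oddball") c("content", "roi")
             else c("valence", "content", "rate_hz")
    tbl <- screen_outliers(tbl, cells, "y", scale_constant, threshold)
  }
  tibble::as_tibble(tbl)
}

#' Fit a random-intercept linear mixed model with type-III F tests
#'
#' Fits the specified model by restricted maximum likelihood with a random
#' intercept per subject and returns type-III F tests for every fixed term,
#' using the Satterthwaite denominator-degrees-of-freedom approximation.
#' On balanced data with zero random-effect variance these F statistics
#' coincide with the fixed-effects ANOVA. Models 2 and 3 refuse control-group
#' rows (they are defined within the adversity group).
#'
#' @param spec A [model_spec()] (or a formula, taken as-is).
#' @param table Modelling table from [build_model_table()].
#' @return Object of class `lmm_result`: `fit` (the `lmerModLmerTest`
#'   object), `effects` (tibble: term, F, df1, df2, p), `spec`,
#'   `ddf_method`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_control = 10, n_adversity = 10, seed = 2))
#' res <- fit_lmm(model_spec(1, "oddball"), build_model_table(sim, "oddball"))
#' res$effects
#' @export
fit_lmm <- function(spec, table) {
  formula <- if (inherits(spec, "model_spec")) spec$formula else spec
  if (inherits(spec, "model_spec") && spec$group_scope == "adversity" &&
      "group" %in% names(table) && any(table$group == "control")) {
    stop("Models 2 and 3 are defined within the adversity group; ",
         "remove control-group rows (build_model_table(..., model = ",
         spec$model, ") does this).")
  }
  fit <- withCallingHandlers(
    lmerTest::lmer(formula, data = table, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage")
  )
  dropped <- attr(lme4::getME(fit, "X"), "col.dropped")
  if (!is.null(dropped)) {
    stop("Rank-deficient fixed-effect design; aliased terms: ",
         paste(names(dropped), collapse = ", "))
  }
  conv <- fit@optinfo$conv$lme4$messages
  if (any(grepl("failed to converge", conv %||% character(0)))) {
    stop("Mixed model failed to converge: ", paste(conv, collapse = "; "))
  }
  a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  effects <- tibble::tibble(
    term = rownames(a), F = a[["F value"]], df1 = a$NumDF, df2 = a$DenDF,
    p = a[["Pr(>F)"]]
  )
  structure(
    list(fit = fit, effects = effects, spec = spec,
         ddf_method = "Satterthwaite"),
    class = "lmm_result"
  )
}

#' @exportS3Method base::print
print.lmm_result <- function(x, ...) {
  if (inherits(x$spec, "model_spec")) {
    cat(sprintf("<lmm_result> Model %d (%s), type-III F (%s df):\n",
                x$spec$model, x$spec$outcome, x$ddf_method))
  } else cat(sprintf("<lmm_result> type-III F (%s df):\n", x$ddf_method))
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' Tukey-corrected pairwise contrasts of estimated marginal means
#'
#' @param result An [fit_lmm()] result (or a fitted `lmer` model).
#' @param specs emmeans specification, e.g. `~ group : content` for all cell
#'   pairs or `~ content | group` for within-group comparisons.
#' @return Tibble: contrast (and any `by` columns), estimate, SE, df,
#'   t, p_tukey.
#' @examples
#' sim <- simulate_cohort(sim_config(n_control = 10, n_adversity = 10, seed = 2))
#' res <- fit_lmm(model_spec(1, "oddball"), build_model_table(sim, "oddball"))
#' tukey_contrasts(res, ~ content | group)
#' @export
tukey_contrasts <- function(result, specs) {
  fit <- if (inherits(result, "lmm_result")) result$fit else result
  emm <- suppressMessages(
    emmeans::emmeans(fit, specs, lmer.df = "satterthwaite")
  )
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  out <- tibble::as_tibble(as.data.frame(prs))
  names(out)[names(out) == "t.ratio"] <- "t"
  names(out)[names(out) == "p.value"] <- "p_tukey"
  out
}

#' Correlation between preferential looking and neural salience
#'
#' For every subject present in both tables, the negative-minus-neutral
#' difference score is computed for the gaze proportions and for the neural
#' salience (averaging each valence's cells within content), and the Pearson
#' correlation between the two difference scores is returned per content
#' context with its n - 2 degrees of freedom.
#'
#' @param gaze Tibble with columns subject, valence, content and the gaze
#'   outcome in `value_col`.
#' @param neural Same structure for the neural-salience outcome.
#' @param value_col Outcome column name in both tables.
#' @return Tibble: content, n, df, r, p.
#' @export
gaze_neural_correlation <- function(gaze, neural, value_col = "y") {
  diff_scores <- function(tbl) {
    wide <- stats::aggregate(tbl[[value_col]],
                             by = list(subject = tbl$subject,
                                       content = tbl$content,
                                       valence = tbl$valence),
                             FUN = mean)
    neg <- wide[wide$valence == "negative", ]
    neu <- wide[wide$valence == "neutral", ]
    m <- merge(neg, neu, by = c("subject", "content"),
               suffixes = c("_neg", "_neu"))
    m$diff <- m$x_neg - m$x_neu
    m[c("subject", "content", "diff")]
  }
  g <- diff_scores(gaze)
  nn <- diff_scores(neural)
  both <- merge(g, nn, by = c("subject", "content"),
                suffixes = c("_gaze", "_neural"))
  out <- lapply(split(both, both$content), function(d) {
    if (nrow(d) < 3) stop("Need at least 3 paired subjects per context.")
    ct <- stats::cor.test(d$diff_gaze, d$diff_neural, method = "pearson")
    tibble::tibble(content = d$content[1], n = nrow(d), df = nrow(d) - 2L,
                   r = unname(ct$estimate), p = ct$p.value)
  })
  dplyr::bind_rows(out)
}

## ---- estimated-effect helpers (sign / magnitude extraction) --------------

#' Difference of estimated marginal means between two factor levels
#'
#' @param result [fit_lmm()] result or fitted model.
#' @param factor Factor name.
#' @param hi,lo Level names; the returned estimate is `hi - lo`.
#' @return Named list with the estimate.
#' @export
emm_diff <- function(result, factor, hi, lo) {
  fit <- if (inherits(result, "lmm_result")) result$fit else result
  emm <- as.data.frame(suppressMessages(
    emmeans::emmeans(fit, stats::reformulate(factor),
                     lmer.df = "asymptotic")
  ))
  est <- emm$emmean[emm[[factor]] == hi] - emm$emmean[emm[[factor]] == lo]
  list(estimate = est)
}

#' Interaction gap between two factors from estimated marginal means
#'
#' Returns `((f1=hi1, f2=hi2) - (hi1, lo2)) - ((lo1, hi2) - (lo1, lo2))`,
#' i.e. how much the `f2` effect differs between the two `f1` levels.
#'
#' @param result [fit_lmm()] result or fitted model.
#' @param f1,f2 Factor names.
#' @param hi1,lo1,hi2,lo2 Level names.
#' @return Named list with the estimate.
#' @export
emm_interaction_gap <- function(result, f1, hi1, lo1, f2, hi2, lo2) {
  fit <- if (inherits(result, "lmm_result")) result$fit else result
  emm <- as.data.frame(suppressMessages(
    emmeans::emmeans(fit, stats::reformulate(c(f1, f2)),
                     lmer.df = "asymptotic")
  ))
  cell <- function(a, b) emm$emmean[emm[[f1]] == a & emm[[f2]] == b]
  list(estimate = (cell(hi1, hi2) - cell(hi1, lo2)) -
         (cell(lo1, hi2) - cell(lo1, lo2)))
}

#' Difference in a covariate's slope between two factor levels
#'
#' @param result [fit_lmm()] result or fitted model.
#' @param var Continuous predictor name.
#' @param factor Moderating factor.
#' @param hi,lo Level names; returns slope(hi) - slope(lo).
#' @return Named list with the estimate.
#' @export
trend_gap <- function(result, var, factor, hi, lo) {
  fit <- if (inherits(result, "lmm_result")) result$fit else result
  tr <- as.data.frame(suppressMessages(
    emmeans::emtrends(fit, stats::reformulate(factor),
                      var = var, lmer.df = "asymptotic")
  ))
  slope <- tr[[paste0(var, ".trend")]]
  list(estimate = slope[tr[[factor]] == hi] - slope[tr[[factor]] == lo])
}
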