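test_that("MAD screening matches the hand-computed robust z-scores", {
  flags <- mad_outliers(c(1, 2, 3, 100))
  expect_equal(flags, c(FALSE, FALSE, FALSE, TRUE))
  # |100 - 2.5| / (1.4826 * 1) = 65.76 > 3
  expect_equal(abs(100 - 2.5) / (1.4826 * 1), 65.76, tolerance = 0.01)
  expect_warning(f0 <- mad_outliers(rep(5, 10)), "zero")
  expect_false(any(f0))
  expect_error(mad_outliers(c(1, 2)), "at least 3")
})

test_that("MAD flag rate on clean Gaussian data matches the normal tail", {
  set.seed(99)
  rates <- replicate(40, mean(mad_outliers(rnorm(1000))))
  expect_lt(abs(mean(rates) - 2 * (1 - pnorm(3))), 0.002)
})

test_that("per-cell screening logs removals and keeps clean cells intact", {
  tbl <- data.frame(
    roi = rep(c("LOT", "MO"), each = 20),
    y = c(rnorm(19), 50, rnorm(20))
  )
  out <- screen_outliers(tbl, "roi")
  expect_equal(attr(out, "n_removed"), 1)
  expect_equal(sum(attr(out, "outlier_log")$n_flagged), 1)
  expect_equal(nrow(out), 39)
})

test_that("standardization yields exact z-scores and is affine-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 4)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_equal(standardize(3 * x + 7), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "SD is zero")
})

test_that("the mixed-model F tests match the closed-form ANOVA oracle", {
  # balanced 2x2 (between x within), no subject effect: the REML fit drives
  # the random-intercept variance to ~0 and the type-III F tests must agree
  # with the fixed-effects two-way ANOVA
  set.seed(42)
  n <- 10
  d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)), B = c("b1", "b2"))
  d$A <- ifelse(as.integer(sub("s", "", d$subject)) <= n, "a1", "a2")
  # antisymmetric within-subject noise: every subject's mean residual is 0,
  # so the REML random-intercept variance estimate is exactly 0
  eps <- rnorm(2 * n)
  d$y <- ifelse(d$B == "b1", eps, -eps) + ifelse(d$A == "a1", 0.4, 0) +
    ifelse(d$B == "b1", -0.3, 0)
  d$A <- factor(d$A); d$B <- factor(d$B)
  contrasts(d$A) <- contr.sum(2); contrasts(d$B) <- contr.sum(2)
  res <- fit_lmm(y ~ A * B + (1 | subject), d)
  oracle <- anova2_oracle(d$y, d$A, d$B)
  eff <- res$effects
  expect_equal(eff$F[eff$term == "A"], oracle$F_A, tolerance = 1e-6)
  expect_equal(eff$F[eff$term == "B"], oracle$F_B, tolerance = 1e-6)
  expect_equal(eff$F[eff$term == "A:B"], oracle$F_AB, tolerance = 1e-6)
})

test_that("model tables restrict, standardize and code factors as documented", {
  sim <- simulate_cohort(sim_config(n_control = 12, n_adversity = 12, seed = 2))
  t1 <- build_model_table(sim, "oddball", model = 1)
  expect_setequal(levels(t1$roi), c("LOT", "MO", "ROT"))
  expect_equal(unname(contrasts(t1$group)[, 1]), c(1, -1))
  expect_equal(mean(t1$adversity), 0, tolerance = 1e-9)
  expect_equal(sd(t1$adversity), 1, tolerance = 1e-9)
  t2 <- build_model_table(sim, "oddball", model = 2)
  expect_true(all(t2$group == "adversity"))
  expect_equal(mean(t2$threat), 0, tolerance = 1e-9)
})

test_that("Models 2 and 3 refuse control-group rows", {
  sim <- simulate_cohort(sim_config(n_control = 12, n_adversity = 12, seed = 2))
  t1 <- build_model_table(sim, "oddball", model = 1)
  expect_error(fit_lmm(model_spec(2, "oddball"), t1), "adversity group")
  expect_error(fit_lmm(model_spec(3, "oddball"), t1), "adversity group")
})

test_that("Tukey correction is inert for a single comparison and scales as k(k-1)/2", {
  sim <- simulate_cohort(sim_config(n_control = 12, n_adversity = 12, seed = 6))
  res <- fit_lmm(model_spec(1, "oddball"), build_model_table(sim, "oddball"))
  two <- tukey_contrasts(res, ~ content)
  expect_equal(nrow(two), 1)
  raw <- summary(emmeans::contrast(
    suppressMessages(emmeans::emmeans(res$fit, ~ content)),
    method = "pairwise", adjust = "none"
  ))
  expect_equal(two$p_tukey, raw$p.value, tolerance = 1e-9)
  six <- tukey_contrasts(res, ~ content:roi)
  expect_equal(nrow(six), 6 * 5 / 2)
  expect_true(all(six$p_tukey >= 0 & six$p_tukey <= 1))
})

test_that("gaze-neural correlation is computed on paired difference scores", {
  sim <- simulate_cohort(sim_config(n_control = 20, n_adversity = 20, seed = 9))
  # y = x: feeding the same table twice gives r = 1 per context
  cc <- gaze_neural_correlation(sim$gaze, sim$gaze)
  expect_equal(cc$r, c(1, 1), tolerance = 1e-12)
  expect_equal(cc$df, c(38L, 38L))
  cc2 <- gaze_neural_correlation(sim$gaze, sim$multiinput_neural)
  expect_true(all(cc2$r > 0.2))  # shared latent factor induces correlation
  tiny <- sim$gaze[sim$gaze$subject %in% c("s001", "s002"), ]
  expect_error(gaze_neural_correlation(tiny, tiny), "at least 3")
})

test_that("independent measures give near-zero correlation on average", {
  cfg <- sim_config(n_control = 25, n_adversity = 25, gaze_neural_loading = 0,
                    neural_sens_sd = 0, gaze_sens_sd = 0, seed = 1)
  rs <- sapply(1:20, function(s) {
    sim <- simulate_cohort(cfg, seed = s)
    mean(gaze_neural_correlation(sim$gaze, sim$multiinput_neural)$r)
  })
  expect_lt(abs(mean(rs)), 0.1)
})
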