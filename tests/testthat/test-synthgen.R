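test_that("identical config and seed give bit-identical EEG recordings", {
  cfg <- sim_config(seed = 77, duration_s = 20)
  r1 <- simulate_eeg(oddball_paradigm(), cfg, "s01")
  r2 <- simulate_eeg(oddball_paradigm(), cfg, "s01")
  expect_identical(r1$samples, r2$samples)
  # different subject or condition decouples the draws
  r3 <- simulate_eeg(oddball_paradigm(), cfg, "s02")
  expect_false(identical(r1$samples, r3$samples))
})

test_that("noise-free spectra equal configured amplitudes at every tagged bin", {
  cfg <- quiet_config(oddball_uv = c(0.3, 0.25, 0.2, 0.15, 0.1),
                      base_uv = c(1, 0.5, 0.2, 0.1), duration_s = 60)
  rec <- simulate_eeg(oddball_paradigm(), cfg, "s01")
  sp <- compute_spectrum(rec)
  for (i in seq_len(nrow(rec$components))) {
    k <- target_bin(sp, rec$components$freq_hz[i])
    expect_equal(unname(sp$amplitudes_uv["P7", k + 1L]),
                 rec$components$amplitude_uv[i], tolerance = 1e-9)
  }
  tagged <- target_bin(sp, rec$components$freq_hz[1])
  all_tagged <- vapply(rec$components$freq_hz, function(f) target_bin(sp, f),
                       integer(1))
  expect_lt(max(sp$amplitudes_uv["P7", -(all_tagged + 1L)]), 1e-9)
})

test_that("multi-input rates are snapped onto the bin grid and recorded", {
  cfg <- sim_config(seed = 5, duration_s = 60)
  rec <- simulate_eeg(multi_input_paradigm(), cfg, "s01")
  expect_equal(unname(rec$paradigm$stream_rates_hz["stream1"]), 277 / 60)
  expect_equal(unname(rec$paradigm$stream_rates_hz["stream2"]), 5)
  # harmonics in the signal are exact multiples of the snapped fundamental
  h2 <- rec$components$freq_hz[rec$components$role == "stream1"][2]
  expect_equal(h2, 2 * 277 / 60)
  expect_error(
    simulate_eeg(multi_input_paradigm(), cfg, "s01", snap = FALSE),
    "4.61"
  )
})

test_that("zero oddball amplitudes leave no oddball response to recover", {
  cfg <- quiet_config(oddball_uv = rep(0, 5), base_uv = c(1, 0.5, 0.2, 0.1),
                      duration_s = 20)
  sp <- compute_spectrum(simulate_eeg(oddball_paradigm(), cfg, "s01"))
  hs <- enumerate_harmonics(1.25, 5, exclude_multiples_of_hz = 5)
  s <- summed_response(sp, hs, "MO")
  expect_lt(abs(s$summed_baseline_subtracted_uv), 1e-9)
})

test_that("cohort generation is seed-stable and obeys configured group sizes", {
  cfg <- sim_config(n_control = 8, n_adversity = 9, seed = 12)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(s1$oddball$y, s2$oddball$y)
  expect_equal(table(s1$covariates$group)[["control"]], 8)
  expect_equal(table(s1$covariates$group)[["adversity"]], 9)
  expect_equal(nrow(s1$oddball), 17 * 2 * 3)
  expect_equal(nrow(s1$multiinput_neural), 17 * 2 * 2 * 2)
})

test_that("cohort ground-truth cell means equal the configured effects", {
  cfg <- sim_config(n_control = 30, n_adversity = 30, within_sd = 0.4,
                    group_content_gap = 1.2, roi_effect_scale = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  d <- merge(sim$oddball, sim$covariates[c("subject", "group")])
  gap <- function(g) {
    m <- tapply(d$y_true[d$group == g], d$content[d$group == g], mean)
    m[["social"]] - m[["nonsocial"]]
  }
  expect_equal(gap("control"), 1.2 * 0.4, tolerance = 1e-12)
  expect_equal(gap("adversity"), 0, tolerance = 1e-12)
  # valence effect on the multi-input truth, content-averaged
  cfg2 <- sim_config(n_control = 30, n_adversity = 30, within_sd = 0.4,
                     valence_effect = 0.9, valence_content_interaction = 0,
                     neural_sens_sd = 0, seed = 3)
  sim2 <- simulate_cohort(cfg2)
  m <- tapply(sim2$multiinput_neural$y_true, sim2$multiinput_neural$valence,
              mean)
  expect_equal(m[["neutral"]] - m[["negative"]], 0.9 * 0.4, tolerance = 1e-12)
})

test_that("fixation streams honour dwell probabilities and calibration scatter", {
  cfg <- sim_config(n_fixations = 400, calibration_error_px = 25, seed = 21)
  aois <- default_aois()
  fx <- simulate_fixations(cfg, aois,
                           dwell_probabilities = c(negative = 1, neutral = 0,
                                                   outside = 0),
                           calibration_error_px = 1e-9)
  a <- aois$negative
  expect_true(all(fx$x_px >= a$x_min & fx$x_px <= a$x_max))
  expect_true(all(fx$y_px >= a$y_min & fx$y_px <= a$y_max))
  expect_true(all(fx$target == "negative"))

  fx2 <- simulate_fixations(cfg, aois, subject_id = "s09")
  expect_equal(mean(fx2$target == "neutral"), 0.5, tolerance = 3 / sqrt(400))
  expect_error(
    simulate_fixations(cfg, aois,
                       dwell_probabilities = c(negative = 0.5, neutral = 0.2,
                                               outside = 0.2)),
    "sum to 1"
  )
})
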