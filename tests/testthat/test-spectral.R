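test_that("a pure sinusoid reads its amplitude at its bin and nothing elsewhere", {
  cfg <- quiet_config(oddball_uv = rep(0, 5), base_uv = c(2, 0, 0, 0),
                      duration_s = 60)
  rec <- simulate_eeg(oddball_paradigm(), cfg, "s01")
  sp <- compute_spectrum(rec)
  k <- target_bin(sp, 5)
  expect_equal(unname(sp$amplitudes_uv["Oz", k + 1L]), 2,
               tolerance = 1e-9)
  expect_lt(max(sp$amplitudes_uv["Oz", -(k + 1L)]), 1e-9)
  expect_equal(sp$freq_resolution_hz, 1 / 60)
})

test_that("spectra are linear: two superposed sines keep their amplitudes", {
  cfg <- quiet_config(oddball_uv = c(0.5, 0, 0, 0, 0),
                      base_uv = c(2, 0, 0, 0), duration_s = 60)
  sp <- compute_spectrum(simulate_eeg(oddball_paradigm(), cfg, "s01"))
  expect_equal(unname(sp$amplitudes_uv["Iz", target_bin(sp, 1.25) + 1L]),
               0.5, tolerance = 1e-9)
  expect_equal(unname(sp$amplitudes_uv["Iz", target_bin(sp, 5) + 1L]), 2,
               tolerance = 1e-9)
  others <- sp$amplitudes_uv["Iz", -(c(target_bin(sp, 1.25),
                                       target_bin(sp, 5)) + 1L)]
  expect_lt(max(others), 1e-9)
})

test_that("constant signals put all mass in the DC bin (removed by detrending)", {
  rec <- list(samples = matrix(3.3, nrow = 1, ncol = 500,
                               dimnames = list("Oz", NULL)),
              sampling_rate_hz = 100, channel_labels = "Oz")
  sp <- compute_spectrum(rec)
  expect_lt(max(sp$amplitudes_uv), 1e-12)  # mean removal zeroes a constant
  expect_error(compute_spectrum(rec, window = c(2, 2.001)), "empty")
})

test_that("target_bin maps aligned frequencies and rejects misaligned ones", {
  expect_identical(target_bin(0.25, 5), 20L)
  expect_identical(target_bin(1 / 60, 1.25), 75L)
  expect_error(target_bin(0.25, 5.1), "not bin-aligned")
})

test_that("neighborhood honours size, adjacency exclusion and spectrum edges", {
  nb <- neighborhood(500, 100, 10, 1)
  expect_setequal(nb$neighbor_bins, c(89:98, 102:111))
  nb0 <- neighborhood(500, 100, 10, 0)
  expect_setequal(nb0$neighbor_bins, c(90:99, 101:110))
  expect_error(neighborhood(500, 5, 10, 1), "edge")
})

test_that("bin_stats matches a brute-force recomputation on a toy spectrum", {
  set.seed(7)
  amps <- abs(rnorm(32, 1, 0.3))
  sp <- toy_spectrum(amps)
  st <- bin_stats(sp, "Oz", frequency_hz = 15 * 0.25)
  nb <- c(15 - 11:2, 15 + 2:11) + 1L  # brute force from the definition
  expect_equal(st$snr, amps[16] / mean(amps[nb]))
  expect_equal(st$baseline_subtracted_uv, amps[16] - mean(amps[nb]))
  expect_equal(st$z, (amps[16] - mean(amps[nb])) / sd(amps[nb]))
})

test_that("bin_stats handles the stated worked examples and sentinels", {
  amps <- rep(1, 41); amps[21] <- 2
  expect_warning(st <- bin_stats(toy_spectrum(amps), "Oz", 20 * 0.25),
                 "SD")
  expect_equal(st$snr, 2)
  expect_equal(st$baseline_subtracted_uv, 1)
  expect_true(is.infinite(st$z) && st$z > 0)

  # neighbours mean 1, sd 0.5, target 2 -> z = 2
  amps <- rep(c(0.5, 1.5), 21)[1:41]; amps[21] <- 2
  st <- bin_stats(toy_spectrum(amps), "Oz", 20 * 0.25)
  expect_equal(st$z, (2 - mean(amps[c(10:19, 23:32)])) /
                 sd(amps[c(10:19, 23:32)]))

  expect_warning(
    expect_warning(st0 <- bin_stats(toy_spectrum(rep(0, 41)), "Oz", 20 * 0.25),
                   "SNR"),
    "SD"
  )
  expect_true(is.nan(st0$snr))
})

test_that("scaling the time series scales amplitudes but not SNR or z", {
  cfg <- sim_config(seed = 33, duration_s = 20)
  rec <- simulate_eeg(oddball_paradigm(), cfg, "s01")
  rec2 <- rec
  rec2$samples <- rec$samples * 3
  s1 <- bin_stats(compute_spectrum(rec), "Oz", 1.25)
  s2 <- bin_stats(compute_spectrum(rec2), "Oz", 1.25)
  expect_equal(s2$amplitude_uv, 3 * s1$amplitude_uv)
  expect_equal(s2$baseline_subtracted_uv, 3 * s1$baseline_subtracted_uv)
  expect_equal(s2$snr, s1$snr, tolerance = 1e-12)
  expect_equal(s2$z, s1$z, tolerance = 1e-12)
})

test_that("white-noise spectra are calibrated: SNR near 1, zero mean baseline", {
  cfg <- sim_config(noise_pink_scale_uv = 0, subject_amp_sdlog = 0,
                    oddball_uv = rep(0, 5), base_uv = rep(0, 4),
                    stream_uv = rep(0, 4), duration_s = 20, seed = 9)
  sp <- compute_spectrum(simulate_eeg(oddball_paradigm(), cfg, "s01"))
  bins <- seq(target_bin(sp, 2), target_bin(sp, 40))
  stats_tbl <- vapply(bins[seq(1, length(bins), by = 2)], function(k) {
    f <- k * sp$freq_resolution_hz
    st <- bin_stats(sp, "Oz", f)
    c(st$snr, st$baseline_subtracted_uv)
  }, numeric(2))
  expect_equal(mean(stats_tbl[1, ]), 1, tolerance = 0.1)
  expect_lt(abs(mean(stats_tbl[2, ])), 0.005)
})
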