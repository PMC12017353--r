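test_that("harmonic enumeration reproduces the analysis frequency structure", {
  odd <- enumerate_harmonics(1.25, 5, exclude_multiples_of_hz = 5)
  expect_equal(odd$retained_hz, c(1.25, 2.5, 3.75, 6.25, 7.5))
  expect_equal(odd$excluded_hz, 5)
  expect_equal(enumerate_harmonics(4.61, 4)$retained_hz,
               c(4.61, 9.22, 13.83, 18.44))
  expect_equal(enumerate_harmonics(5, 4)$retained_hz, c(5, 10, 15, 20))
})

test_that("exclusion uses exact rational coincidence, not float equality", {
  # 0.1 * 3 != 0.3 in floating point, yet the 3rd harmonic must be excluded
  h <- enumerate_harmonics(0.1, 5, exclude_multiples_of_hz = 0.3)
  expect_equal(h$retained_hz, c(0.1, 0.2, 0.4, 0.5, 0.7))
})

test_that("consecutive-failure rule keeps the prefix before the first double miss", {
  expect_equal(select_significant(rep(3, 6))$retained, 6)
  expect_equal(select_significant(rep(0, 6))$retained, 0)
  expect_equal(select_significant(c(2.1, 1.9, 1.7, 1.1, 0.9, 0.5))$retained, 3)
  # an isolated miss flanked by hits does not cut the prefix
  expect_equal(select_significant(c(2.5, 1.2, 2.2, 2.0, 1.0, 0.8))$retained, 4)
  # strict mode drops the isolated miss itself
  sel <- select_significant(c(2.5, 1.2, 2.2, 2.0, 1.0, 0.8), mode = "strict")
  expect_equal(sel$retained, 3)
  expect_equal(which(sel$keep), c(1, 3, 4))
  # the rule is enforced cell-wise: one failing cell fails the harmonic
  z <- cbind(a = c(3, 3, 3, 3), b = c(3, 1, 1, 3))
  expect_equal(select_significant(z)$retained, 1)
  expect_error(select_significant(matrix(numeric(0), ncol = 1)), "Empty")
})

test_that("summed response adds per-harmonic values and averages ROI channels", {
  cfg <- quiet_config(oddball_uv = rep(0.2, 5), base_uv = rep(0, 4),
                      duration_s = 20)
  sp <- compute_spectrum(simulate_eeg(oddball_paradigm(), cfg, "s01"))
  hs <- enumerate_harmonics(1.25, 5, exclude_multiples_of_hz = 5)
  s <- summed_response(sp, hs, "LOT")
  expect_equal(s$summed_baseline_subtracted_uv, 1.0, tolerance = 1e-6)
  # additivity over disjoint harmonic subsets
  k12 <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  s12 <- summed_response(sp, hs, "LOT", keep = k12)
  s345 <- summed_response(sp, hs, "LOT", keep = !k12)
  expect_equal(s12$summed_baseline_subtracted_uv +
                 s345$summed_baseline_subtracted_uv,
               s$summed_baseline_subtracted_uv, tolerance = 1e-9)
  expect_error(summed_response(sp, hs, c("Oz", "Nonexistent")), "missing")
})

test_that("ROI aggregation lies between its channels' per-channel sums", {
  cfg <- sim_config(seed = 4, duration_s = 20,
                    roi_gains = c(LOT = 1, MO = 1.5, ROT = 0.8, other = 0.2))
  sp <- compute_spectrum(simulate_eeg(oddball_paradigm(), cfg, "s01"))
  hs <- enumerate_harmonics(1.25, 5, exclude_multiples_of_hz = 5)
  per_channel <- vapply(roi_definitions("MO")[[1]], function(ch) {
    sum(vapply(hs$retained_hz, function(f) {
      bin_stats(sp, ch, f)$baseline_subtracted_uv
    }, numeric(1)))
  }, numeric(1))
  s <- summed_response(sp, hs, "MO")
  expect_gte(s$summed_baseline_subtracted_uv, min(per_channel) - 1e-12)
  expect_lte(s$summed_baseline_subtracted_uv, max(per_channel) + 1e-12)
})

test_that("group-average ROI z-scores feed harmonic selection", {
  cfg <- sim_config(seed = 8, duration_s = 20, n_control = 2, n_adversity = 2,
                    oddball_uv = c(0.6, 0.5, 0.4, 0, 0), subject_amp_sdlog = 0,
                    noise_white_sd_uv = 0.5, noise_pink_scale_uv = 0.02)
  hs <- enumerate_harmonics(1.25, 5, exclude_multiples_of_hz = 5)
  spectra <- lapply(c("s01", "s02", "s03"), function(s) {
    compute_spectrum(simulate_eeg(oddball_paradigm(), cfg, s))
  })
  z <- harmonic_z_table(list(social = spectra), hs)
  expect_equal(dim(z), c(5L, 3L))
  sel <- select_significant(z)
  expect_gte(sel$retained, 3)  # three strong injected harmonics
  expect_lte(sel$retained, 4)  # prefix may keep at most one trailing miss
})

test_that("averaging spectra requires a common bin grid", {
  cfg1 <- quiet_config(duration_s = 20)
  cfg2 <- quiet_config(duration_s = 40)
  sp1 <- compute_spectrum(simulate_eeg(oddball_paradigm(), cfg1, "s01"))
  sp2 <- compute_spectrum(simulate_eeg(oddball_paradigm(), cfg2, "s01"))
  expect_error(average_spectra(list(sp1, sp2)), "share")
  avg <- average_spectra(list(sp1, sp1))
  expect_equal(avg$amplitudes_uv, sp1$amplitudes_uv)
})
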