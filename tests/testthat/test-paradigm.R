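test_that("oddball paradigm derives the oddball rate from base rate and cycle", {
  p <- oddball_paradigm()
  expect_equal(p$oddball_rate_hz, p$base_rate_hz / p$oddball_cycle)
  expect_equal(p$oddball_rate_hz, 1.25)
  expect_equal(tagged_frequencies(p), c(oddball = 1.25, base = 5))
  expect_error(oddball_paradigm(oddball_cycle = 1), "oddball_cycle")
})

test_that("multi-input paradigm validates distinct rates and valence mapping", {
  p <- multi_input_paradigm()
  expect_setequal(unname(p$valence_assignment), c("negative", "neutral"))
  expect_equal(sort(unname(tagged_frequencies(p))), c(4.61, 5))
  expect_error(
    multi_input_paradigm(stream_rates_hz = c(stream1 = 5, stream2 = 5)),
    "distinct"
  )
})

test_that("ROI definitions carry the standard channel sets and are disjoint", {
  rois <- roi_definitions()
  expect_equal(rois$LOT, c("P7", "P9", "PO7"))
  expect_equal(rois$MO, c("Iz", "Oz", "O1", "O2"))
  expect_equal(rois$ROT, c("P8", "P10", "PO8"))
  all_ch <- unlist(rois)
  expect_equal(anyDuplicated(all_ch), 0L)
})

test_that("sim_config validates layout, probabilities and group sizes", {
  expect_error(sim_config(channels = c("Oz", "O1")), "ROI channels")
  expect_error(sim_config(dwell_probabilities = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(sim_config(n_control = 1), "Group sizes")
})
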