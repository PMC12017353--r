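test_that("fixation weights equal closed-form Gaussian rectangle masses", {
  sigma <- 40
  aois <- list(
    aoi_rect("negative", 500 - sigma, 500 + sigma, -1e6, 1e6),
    aoi_rect("neutral", 5000, 6000, -1e6, 1e6)
  )
  w <- fixation_weights(500, 0, sigma, aois)
  expect_equal(unname(w["negative"]), pnorm(1) - pnorm(-1), tolerance = 1e-9)
  # general off-centre rectangle against the product-of-CDF oracle
  a <- aoi_rect("negative", 420, 610, 350, 520)
  w2 <- fixation_weights(480, 400, 35, list(a))
  oracle <- (pnorm(610, 480, 35) - pnorm(420, 480, 35)) *
    (pnorm(520, 400, 35) - pnorm(350, 400, 35))
  expect_equal(unname(w2["negative"]), oracle, tolerance = 1e-12)
  expect_equal(sum(w2), 1)
})

test_that("weights are symmetric at the midpoint of mirror-image AOIs", {
  aois <- default_aois()
  mid_x <- 1920 / 2
  w <- fixation_weights(mid_x, 540, 50, aois)
  expect_equal(unname(w["negative"]), unname(w["neutral"]), tolerance = 1e-12)
})

test_that("vanishing calibration error degenerates to point-in-rectangle", {
  aois <- default_aois()
  inside <- c(700, 540)   # inside the left rectangle
  w0 <- fixation_weights(inside[1], inside[2], 0, aois)
  expect_equal(unname(w0), c(1, 0, 0))
  for (sd in c(20, 5, 1, 0.1)) {
    w <- fixation_weights(inside[1], inside[2], sd, aois)
    expect_gte(unname(w["negative"]), unname(w0["negative"]) - 1e-3 * sd)
  }
  w_small <- fixation_weights(inside[1], inside[2], 1e-3, aois)
  expect_equal(unname(w_small["negative"]), 1, tolerance = 1e-9)
})

test_that("enlarging a rectangle never decreases its weight", {
  base <- aoi_rect("negative", 400, 600, 300, 500)
  bigger <- aoi_rect("negative", 380, 640, 280, 520)
  for (xy in list(c(500, 400), c(100, 100), c(650, 510))) {
    wb <- fixation_weights(xy[1], xy[2], 45, list(base))
    wB <- fixation_weights(xy[1], xy[2], 45, list(bigger))
    expect_gte(unname(wB["negative"]), unname(wb["negative"]))
  }
})

test_that("proportional looking is the duration-weighted average of weights", {
  aois <- default_aois()
  # one fixation: proportions equal its weights
  fx1 <- data.frame(x_px = 900, y_px = 540, duration_s = 2,
                    calibration_error_px = 120)
  g1 <- proportional_looking(fx1, aois)
  w <- fixation_weights(900, 540, 120, aois)
  expect_equal(g1$proportions, w, tolerance = 1e-12)
  expect_equal(sum(g1$proportions), 1, tolerance = 1e-9)

  # 3 s fully inside A, 1 s fully inside B -> (0.75, 0.25, 0)
  fx2 <- data.frame(x_px = c(700, 1200), y_px = 540, duration_s = c(3, 1),
                    calibration_error_px = 1e-6)
  g2 <- proportional_looking(fx2, aois)
  expect_equal(unname(g2$proportions),
               c(0.75, 0.25, 0), tolerance = 1e-9)

  # non-finite coordinates are dropped, not propagated
  fx3 <- rbind(fx2, data.frame(x_px = NaN, y_px = 540, duration_s = 5,
                               calibration_error_px = 1e-6))
  g3 <- proportional_looking(fx3, aois)
  expect_equal(g3$n_dropped, 1L)
  expect_equal(g3$proportions, g2$proportions)
  expect_error(proportional_looking(fx2[0, ], aois), "No valid fixations")
})

test_that("configured dwell proportions are recovered from simulated streams", {
  cfg <- sim_config(n_fixations = 200, calibration_error_px = 30, seed = 14)
  aois <- default_aois()
  probs <- c(negative = 0.7, neutral = 0.3, outside = 0)
  fx <- simulate_fixations(cfg, aois, dwell_probabilities = probs)
  g <- proportional_looking(fx, aois)
  expect_equal(unname(g$proportions["negative"]), 0.7, tolerance = 0.05)
  expect_equal(unname(g$proportions["neutral"]), 0.3, tolerance = 0.05)
})
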