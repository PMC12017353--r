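# shared fixtures: small, fast configurations used across the suite

# noise-free configuration: exact spectral ground truth, unit topography
quiet_config <- function(..., duration_s = 20) {
  sim_config(
    duration_s = duration_s, n_epochs = 1,
    noise_white_sd_uv = 0, noise_pink_scale_uv = 0, subject_amp_sdlog = 0,
    roi_gains = c(LOT = 1, MO = 1, ROT = 1, other = 1),
    seed = 101, ...
  )
}

# hand-built amplitude spectrum (one channel unless a matrix is given)
toy_spectrum <- function(amplitudes, resolution_hz = 0.25,
                         channel = "Oz") {
  if (is.null(dim(amplitudes))) {
    amplitudes <- matrix(amplitudes, nrow = 1, dimnames = list(channel, NULL))
  }
  structure(
    list(
      amplitudes_uv = amplitudes,
      freq_resolution_hz = resolution_hz,
      frequencies_hz = (seq_len(ncol(amplitudes)) - 1L) * resolution_hz,
      channel_labels = rownames(amplitudes),
      subject_id = "toy", condition = "toy"
    ),
    class = "amplitude_spectrum"
  )
}

# closed-form balanced two-way fixed-effects ANOVA (the independent oracle
# for the mixed-model engine): returns F statistics for A, B and A:B
anova2_oracle <- function(y, A, B) {
  stopifnot(length(unique(table(A, B))) == 1)  # balanced
  n <- length(y)
  a <- nlevels(factor(A)); b <- nlevels(factor(B))
  r <- n / (a * b)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ssA <- r * b * sum((mA - grand)^2)
  ssB <- r * a * sum((mB - grand)^2)
  cellA <- rep(mA, times = b); cellB <- rep(mB, each = a)
  ssAB <- r * sum((mAB - cellA - cellB + grand)^2)
  sse <- sum((y - mAB[interaction(A, B)])^2)
  dfe <- n - a * b
  list(
    F_A = (ssA / (a - 1)) / (sse / dfe),
    F_B = (ssB / (b - 1)) / (sse / dfe),
    F_AB = (ssAB / ((a - 1) * (b - 1))) / (sse / dfe)
  )
}
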