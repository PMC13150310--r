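# Independent oracles used across the suite.

# Brute-force sub-threshold length: densely resample the piecewise-linear
# interpolant and count the sub-threshold fraction of the arc.
dense_threshold_length <- function(positions, values, threshold, step = 0.001) {
  xs <- seq(min(positions), max(positions), by = step)
  v <- stats::approx(positions, values, xout = xs)$y
  sum(v < threshold) * step
}

# Brute-force windowed-minimum mean: evaluate the mean of the dense
# resampled interpolant over every window start on a fine grid.
dense_o2_minimum <- function(positions, values, window, step = 1) {
  xs <- seq(min(positions), max(positions), by = step)
  v <- stats::approx(positions, values, xout = xs)$y
  k <- round(window / step)
  cs <- c(0, cumsum(v))
  means <- (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
  min(means)
}

# Random piecewise-linear O2-like profile on a uniform grid.
random_profile <- function(n_samples = 30, spacing = 5) {
  pos <- seq(0, by = spacing, length.out = n_samples)
  vals <- runif(n_samples, -0.5, 9.7)
  # occasionally inject flat stretches and threshold-grazing values
  if (runif(1) < 0.3) vals[seq(2, n_samples, by = 3)] <- 1.92
  if (runif(1) < 0.3) {
    i <- sample(n_samples - 3, 1)
    vals[i:(i + 3)] <- vals[i]
  }
  o2_profile(pos, vals)
}

# Compact synthetic scene used where full study-scale extents are not
# needed; s_min and the root axis (odd ny) sit exactly on pixel centres and
# the mature rise is far from the tip so the closed-form field minimum is
# at a grid point (s_min, 0).
compact_scene <- function(noise_sd = 0, seed = 1) {
  scene_config(nx = 1500, ny = 401, pixel_size = 2, s_min = 500,
               sigma_L = 200, sigma_T = 100, cap_pos = 250,
               hair_pos = 2750, rise_pos = 2500, rise_width = 100,
               noise_sd = noise_sd, seed = seed)
}

uniform_channel_pair <- function(value = 100, n = 4, pixel_size = 1) {
  list(channel_image(matrix(value, n, n), pixel_size, "sensor"),
       channel_image(matrix(value, n, n), pixel_size, "reference"))
}
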