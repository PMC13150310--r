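test_that("scene field is uniform when both depressions vanish", {
  cfg <- scene_config(nx = 50, ny = 20, dO2_tip = 0, dO2_mat = 0,
                      s_min = 40, cap_pos = 10, hair_pos = 70)
  m <- o2_field(cfg)
  expect_true(all(m$pixels == 9.2))
})

test_that("rendered field minimum matches the closed form at (s_min, 0)", {
  cfg <- compact_scene()
  m <- o2_field(cfg)
  mn <- scene_min(cfg)
  # s_min (500 um) sits on a pixel centre and the mature rise is 10 sigma_L
  # away, so the analytic minimum falls on the grid
  expect_equal(min(m$pixels), mn$value, tolerance = 1e-9)
  expect_equal(mn$s, cfg$s_min, tolerance = 0.01)
  closed_form <- cfg$O2_bg - cfg$dO2_tip -
    cfg$dO2_mat / (1 + exp(-(cfg$s_min - cfg$rise_pos) / cfg$rise_width))
  expect_equal(mn$value, closed_form, tolerance = 1e-9)
})

test_that("transverse suboxic crossing inverts the Gaussian factor", {
  cfg <- compact_scene()
  m <- o2_field(cfg)
  cr <- scene_crossings(cfg, 0.16)
  # rendered crossing: first/last sub-threshold pixel on the minimum column
  col <- round(scene_min(cfg)$s / cfg$pixel_size) + 1L
  d <- (seq_len(cfg$ny) - 1 - cfg$axis_y) * cfg$pixel_size
  below <- which(m$pixels[, col] < 0.16)
  rendered <- d[max(below)] - d[min(below)]
  expect_equal(rendered, cr$transverse_length, tolerance = cfg$pixel_size)
  # closed form: d* = sigma_T * sqrt(2 log(D / (bg - threshold)))
  D <- cfg$O2_bg - scene_min(cfg)$value
  expect_equal(cr$transverse_length,
               2 * cfg$sigma_T * sqrt(2 * log(D / (cfg$O2_bg - 0.16))),
               tolerance = 1e-9)
})

test_that("noiseless rendering round-trips through calibration exactly", {
  cfg <- compact_scene(noise_sd = 0)
  truth <- o2_field(cfg)
  ch <- render_channels(truth, cfg)
  rec <- ratio_to_o2(compute_ratio(ch$sensor, ch$reference), cfg$fit)
  expect_lt(max(abs(rec$pixels - truth$pixels)), 1e-9)

  # O2 at air saturation everywhere -> R = R_air everywhere
  flat <- o2_map(matrix(9.2, 10, 10), cfg$pixel_size)
  chf <- render_channels(flat, cfg)
  expect_equal(chf$sensor$pixels / chf$reference$pixels,
               matrix(cfg$fit$R_air, 10, 10), tolerance = 1e-12)

  bad <- o2_map(matrix(cfg$fit$C - 1, 5, 5), cfg$pixel_size)
  expect_error(render_channels(bad, cfg), "invertibility")
})

test_that("channel noise propagates per the first-order error bound", {
  cfg <- compact_scene(noise_sd = 0.01, seed = 4)
  truth <- o2_field(cfg)
  ch <- render_channels(truth, cfg)
  rec <- ratio_to_o2(compute_ratio(ch$sensor, ch$reference), cfg$fit)
  err <- rec$pixels - truth$pixels
  expect_lt(abs(median(err)), 0.01)
  # delta method: sd(O2) ~ 2 (O2 - C) R sd_rel, sd_rel = 0.01 sqrt(2)
  R <- -0.5 * log((truth$pixels - cfg$fit$C) / cfg$fit$A)
  bound <- 2 * (truth$pixels - cfg$fit$C) * R * 0.01 * sqrt(2)
  expect_gte(mean(abs(err) <= 1.96 * bound), 0.94)
})

test_that("rendered channel intensities are non-negative and seeded runs repeat", {
  cfg <- compact_scene(noise_sd = 0.05, seed = 12)
  truth <- o2_field(cfg)
  a <- render_channels(truth, cfg)
  b <- render_channels(truth, cfg)
  expect_identical(a$sensor$pixels, b$sensor$pixels)
  expect_identical(a$reference$pixels, b$reference$pixels)
  expect_gte(min(a$sensor$pixels), 0)
  expect_gte(min(a$reference$pixels), 0)

  r1 <- simulate_exp2_records(experiment_config(seed = 6))
  r2 <- simulate_exp2_records(experiment_config(seed = 6))
  expect_identical(r1, r2)
})

test_that("timelapse generator encodes the light/dark and treatment effects", {
  cfg <- experiment_config()
  sim <- simulate_timelapse(cfg, treatment = "Sterile", hours = 47,
                            noise = FALSE, seed = 1)
  tr <- sim$truth
  # constant rate, no noise: all instantaneous rates at the process mean
  expect_true(all(tr$instantaneous_rate == cfg$rate_mean))
  rec <- build_growth_records(sim$track)
  expect_true(all(rec$growth_rate == cfg$rate_mean))
  # Sterile: dark records exceed light records by the dark offset
  dark_mean <- mean(tr$true_o2_min[tr$period == "dark"])
  light_mean <- mean(tr$true_o2_min[tr$period == "light"])
  expect_equal(dark_mean - light_mean, 1.46, tolerance = 1e-10)

  soil <- simulate_timelapse(cfg, treatment = "SoilCommunity", hours = 47,
                             noise = FALSE, seed = 1)$truth
  expect_equal(mean(soil$true_o2_min[soil$period == "dark"]) -
                 mean(soil$true_o2_min[soil$period == "light"]),
               1.46 - 1.99, tolerance = 1e-10)
})

test_that("gradient-experiment tables reproduce the nested design", {
  cfg <- experiment_config()
  e1 <- simulate_experiment1(cfg, seed = 2)
  expect_equal(length(unique(e1$root)), 36)
  expect_equal(length(unique(e1$device)), 10)
  expect_equal(length(unique(e1$treatment)), 3)
  expect_equal(nrow(e1), 36 * 7)

  e0 <- simulate_experiment1(cfg, seed = 2, sd_scale = 0)
  means <- exp1_metric_defaults()$means
  for (tr in colnames(means)) {
    sub <- e0[e0$treatment == tr, rownames(means)]
    expect_true(all(abs(t(sub) - means[, tr]) < 1e-12))
  }
})
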