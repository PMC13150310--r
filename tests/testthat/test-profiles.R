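test_that("sample_profile reproduces constant, linear and bilinear fields", {
  const <- o2_map(matrix(4.4, 20, 30), 2)
  line <- polyline(rbind(c(1, 5), c(25, 12)), "transverse")
  p <- sample_profile(const, line)
  expect_equal(p$values, rep(4.4, length(p$values)), tolerance = 1e-12)
  expect_equal(p$positions[1], 0)

  # O2(x, y) = x * pixel_size: bilinear sampling preserves a linear field
  lin <- o2_map(matrix(rep((0:29) * 2, each = 20), 20, 30), 2)
  ph <- sample_profile(lin, polyline(rbind(c(0, 10), c(29, 10)), "longitudinal"))
  expect_equal(ph$values, ph$positions, tolerance = 1e-12)

  # centre of a 2x2 checkerboard of 0/9.2 is the mean of the four corners
  chk <- o2_map(matrix(c(0, 9.2, 9.2, 0), 2, 2), 1)
  pd <- sample_profile(chk, polyline(rbind(c(0, 0), c(1, 1)), "transverse"),
                       spacing = sqrt(2) / 2)
  expect_equal(pd$values[2], 4.6, tolerance = 1e-12)

  expect_error(sample_profile(const, polyline(rbind(c(0, 0), c(40, 0)),
                                              "longitudinal")),
               "bounds")
})

test_that("masked pixels poison interpolated samples", {
  px <- matrix(5, 10, 10); mask <- matrix(TRUE, 10, 10)
  mask[5, 5] <- FALSE; px[5, 5] <- NA
  m <- o2_map(px, 1, mask)
  p <- sample_profile(m, polyline(rbind(c(0, 4), c(9, 4)), "longitudinal"))
  expect_true(any(is.na(p$values)))
  expect_false(is.na(p$values[1]))
})

test_that("longitudinal normalization maps cap to 0 and hairs to 1", {
  pos <- seq(0, 1200, by = 50)
  p <- o2_profile(pos, rep(5, length(pos)), cap_pos = 0, hair_pos = 1000)
  np <- normalize_longitudinal(p)
  # sample at 750 um with cap 0 / hairs 1000 -> relative position 0.75
  expect_true(any(abs(np$rel_positions - 0.75) < 1e-12))
  expect_true(all(np$rel_positions >= 0 & np$rel_positions <= 1))

  p2 <- o2_profile(seq(0, 1400, 100), rnorm(15) + 5, cap_pos = 200, hair_pos = 1200)
  np2 <- normalize_longitudinal(p2)
  expect_identical(np2$rel_positions[1], 0)
  expect_identical(np2$rel_positions[length(np2$rel_positions)], 1)
  expect_equal(np2$scale, 1000)

  # enumeration: cap 100, hairs 1100, samples every 100 um from 0 to 1200
  p3 <- o2_profile(seq(0, 1200, 100), seq(0, 1200, 100) / 100,
                   cap_pos = 100, hair_pos = 1100)
  np3 <- normalize_longitudinal(p3)
  expect_equal(np3$rel_positions, seq(0, 1, by = 0.1))
  expect_length(np3$rel_positions, 11)

  expect_error(normalize_longitudinal(o2_profile(0:5 * 10, rep(1, 6))),
               "landmark")
})

test_that("normalization is invariant to uniform rescaling of positions", {
  set.seed(1)
  vals <- runif(21, 0, 9.2)
  p1 <- o2_profile(seq(0, 2000, 100), vals, cap_pos = 200, hair_pos = 1800)
  p2 <- o2_profile(seq(0, 4000, 200), vals, cap_pos = 400, hair_pos = 3600)
  n1 <- normalize_longitudinal(p1); n2 <- normalize_longitudinal(p2)
  expect_equal(n1$rel_positions, n2$rel_positions)
  expect_equal(n1$values, n2$values)
})

test_that("mature-zone mean averages the 0.75-1.0 window", {
  pos <- seq(0, 1000, 50)
  np <- normalize_longitudinal(o2_profile(pos, rep(4.4, 21),
                                          cap_pos = 0, hair_pos = 1000))
  expect_equal(mean_mature_o2(np), 4.4)

  # only the samples at rel 0.8 and 0.9 fall inside the [0.78, 0.92] window
  v2 <- rep(1, 11); v2[9] <- 4; v2[10] <- 5
  np2 <- normalize_longitudinal(o2_profile(seq(0, 1000, 100), v2,
                                           cap_pos = 0, hair_pos = 1000))
  expect_equal(mean_mature_o2(np2, 0.78, 0.92), 4.5)

  # linear profile v(rel) = 9.2 rel sampled at 0.75, 0.80, ..., 1.00
  np3 <- normalize_longitudinal(o2_profile(seq(0, 1000, 50), 9.2 * seq(0, 1000, 50) / 1000,
                                           cap_pos = 0, hair_pos = 1000))
  expect_equal(mean_mature_o2(np3), 9.2 * 0.875)
  expect_error(mean_mature_o2(np3, 1.5, 1.6), "window")
})

test_that("threshold_length matches hand-computed crossings", {
  p_hi <- o2_profile(seq(0, 500, 10), rep(9.2, 51))
  expect_equal(threshold_length(p_hi, 1.92), 0)

  p_lo <- o2_profile(seq(0, 500, 10), rep(0.1, 51))
  expect_equal(threshold_length(p_lo, 0.16), 500)

  p <- o2_profile(seq(0, 50, 10), c(9.2, 9.2, 1.0, 0.1, 1.0, 9.2))
  expect_equal(threshold_length(p, 1.92),
               dense_threshold_length(p$positions, p$values, 1.92),
               tolerance = 0.01)
  expect_equal(threshold_length(p, 1.92), 22.24, tolerance = 0.01)
  expect_equal(threshold_length(p, 0.16), 1.33, tolerance = 0.01)

  # counting variant: samples below threshold times spacing
  expect_equal(threshold_length(p, 1.92, method = "count"), 30)
})

test_that("interpolated threshold lengths agree with the dense oracle on random profiles", {
  set.seed(7)
  for (i in 1:200) {
    p <- random_profile()
    for (th in c(1.92, 0.16)) {
      expect_lt(abs(threshold_length(p, th) -
                      dense_threshold_length(p$positions, p$values, th)),
                0.01)
    }
    hyp <- threshold_length(p, 1.92); sub <- threshold_length(p, 0.16)
    expect_lte(sub, hyp)
    expect_gte(sub, 0)
    expect_lte(hyp, max(p$positions))
  }
})

test_that("normalized profiles report lengths on the micrometre scale", {
  pos <- seq(0, 1000, 10)
  vals <- ifelse(pos >= 300 & pos <= 500, 0.1, 9.2)
  np <- normalize_longitudinal(o2_profile(pos, vals, cap_pos = 0, hair_pos = 1000))
  expect_equal(threshold_length(np, 1.92),
               dense_threshold_length(pos, vals, 1.92), tolerance = 0.01)
})

test_that("transverse metrics compute the boundary-minus-minimum decrease", {
  # boundaries at saturation, minimum 1.1 -> decrease 8.1
  pos <- seq(0, 400, 10)
  vals <- 9.2 - 8.1 * exp(-(pos - 200)^2 / (2 * 50^2))
  tm <- transverse_metrics(o2_profile(pos, vals, kind = "transverse"))
  expect_equal(tm$max_decrease, mean(c(vals[1], vals[41])) - min(vals))
  expect_equal(tm$max_decrease, 8.1, tolerance = 0.01)
  expect_equal(tm$min_position, 200)
  expect_equal(tm$centered$positions[which.min(tm$centered$values)], 0)

  flat <- transverse_metrics(o2_profile(seq(0, 100, 10), rep(3, 11)))
  expect_equal(flat$max_decrease, 0)

  asym <- transverse_metrics(o2_profile(c(0, 10, 20), c(9, 0, 7)))
  expect_equal(asym$max_decrease, 8)
  expect_gte(asym$max_decrease, 0)
})

test_that("max_decrease is never negative on random profiles", {
  set.seed(3)
  for (i in 1:50) {
    p <- random_profile(20)
    expect_gte(transverse_metrics(p)$max_decrease, 0)
  }
})

test_that("profile averaging returns per-grid mean and SE", {
  pos <- seq(0, 1000, 100)
  mk <- function(v) normalize_longitudinal(
    o2_profile(pos, rep(v, 11), cap_pos = 0, hair_pos = 1000))
  two_same <- average_profiles(list(mk(4), mk(4)))
  expect_true(all(two_same$mean == 4))
  expect_true(all(two_same$se == 0))

  two_diff <- average_profiles(list(mk(4), mk(6)))
  expect_true(all(two_diff$mean == 5))
  expect_true(all(abs(two_diff$se - 1) < 1e-12))

  expect_error(average_profiles(list(mk(4))), ">= 2")
})

test_that("averaging recovers a noisy truth profile within Monte-Carlo bounds", {
  set.seed(11)
  pos <- seq(0, 1000, 20)
  truth <- 9.2 - 8 * exp(-(pos - 300)^2 / (2 * 120^2))
  profs <- lapply(1:100, function(i) normalize_longitudinal(
    o2_profile(pos, truth + rnorm(length(pos), 0, 0.5),
               cap_pos = 0, hair_pos = 1000)))
  avg <- average_profiles(profs)
  truth_on_grid <- approx(pos / 1000, truth, xout = avg$position)$y
  frac_ok <- mean(abs(avg$mean - truth_on_grid) <= 3 * 0.5 / sqrt(100))
  expect_gte(frac_ok, 0.99)
})
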