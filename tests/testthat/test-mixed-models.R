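test_that("noiseless data recover the generating coefficients exactly", {
  cfg <- experiment_config(root_sd = 0, resid_sd = 0)
  rec <- simulate_exp2_records(cfg, seed = 1)
  fit <- fit_lmm(rec, build_exp2_specs()$model2)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(unname(est["(Intercept)"]), 3.58, tolerance = 1e-8)
  expect_equal(unname(est["growth_rate"]), -2.74e-3, tolerance = 1e-8)
  expect_equal(unname(est["treatmentP_protegens"]), -6.42e-3, tolerance = 1e-8)
  expect_equal(unname(est["treatmentSoilCommunity"]), 1.92, tolerance = 1e-8)
  expect_equal(unname(est["perioddark"]), 1.46, tolerance = 1e-8)
  expect_equal(unname(est["treatmentP_protegens:perioddark"]), -0.884, tolerance = 1e-8)
  expect_equal(unname(est["treatmentSoilCommunity:perioddark"]), -1.99, tolerance = 1e-8)
  # degenerate grouping is flagged, not hidden
  expect_true(fit$singular || fit$converged)
})

test_that("without random terms fit_lmm reduces to ordinary least squares", {
  set.seed(21)
  d <- data.frame(y = rnorm(40), g = rep(c("A", "B"), each = 20))
  sp <- model_spec("y", fixed_terms = "g")
  f <- fit_lmm(d, sp)
  # two-group balanced data: estimates are the group means difference
  expect_equal(f$estimates$estimate[2],
               mean(d$y[d$g == "B"]) - mean(d$y[d$g == "A"]),
               tolerance = 1e-12)
  # normal-equations oracle
  X <- cbind(1, as.numeric(d$g == "B"))
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(f$estimates$estimate, as.numeric(beta), tolerance = 1e-12)
})

test_that("a singular mixed fit agrees with OLS on the same fixed effects", {
  # no true between-root variance, and the full fixed structure so no
  # systematic signal can masquerade as grouping variance
  cfg <- experiment_config(root_sd = 0, resid_sd = 0.4, roots_per_treatment = 4)
  rec <- simulate_exp2_records(cfg, seed = 5)
  sp <- build_exp2_specs()$model2
  f_mixed <- fit_lmm(rec, sp)
  f_ols <- fit_lmm(rec, model_spec("o2_min", sp$fixed_terms))
  expect_true(f_mixed$singular)
  expect_equal(unname(f_mixed$variance_components[["treatment:root_id"]]), 0)
  expect_equal(f_mixed$estimates$estimate, f_ols$estimates$estimate,
               tolerance = 1e-10)
})

test_that("variance partition R2 obeys its definition and bounds", {
  set.seed(33)
  d <- data.frame(y = rnorm(60), x = rnorm(60))
  f <- fit_lmm(d, model_spec("y", "x"))
  r2 <- r2_variance_partition(f)
  expect_equal(unname(r2["r2_marginal"]), unname(r2["r2_conditional"]))

  f0 <- fit_lmm(d, model_spec("y"))
  expect_equal(f0$r2_marginal, 0)

  # tuned partition: fixed/random/residual variances 21/33/46 of the total
  set.seed(77)
  n_root <- 240; n_obs <- 20
  a <- sqrt(0.21 * 3 / 2)
  g <- rep(c("A", "B", "C"), length.out = n_root)
  eff <- c(A = -a, B = 0, C = a)
  root <- rep(seq_len(n_root), each = n_obs)
  y <- eff[g[root]] + rep(rnorm(n_root, 0, sqrt(0.33)), each = n_obs) +
    rnorm(n_root * n_obs, 0, sqrt(0.46))
  d2 <- data.frame(y = as.numeric(y), treatment = g[root],
                   root_id = paste0("r", root))
  f2 <- fit_lmm(d2, model_spec("y", "treatment", "root_id"))
  expect_equal(f2$r2_marginal, 0.21, tolerance = 0.04)
  expect_equal(f2$r2_conditional, 0.54, tolerance = 0.04)
  expect_lte(f2$r2_marginal, f2$r2_conditional)
  expect_lte(f2$r2_conditional, 1)
})

test_that("simple regression recovers exact lines and matches normal equations", {
  x <- seq(100, 1200, 50)
  y <- 4.22 - 0.00275 * x
  reg <- simple_regression(x, y)
  expect_equal(reg$slope, -0.00275, tolerance = 1e-12)
  expect_equal(reg$intercept, 4.22, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1)

  regc <- simple_regression(x, rep(2, length(x)))
  expect_equal(regc$slope, 0)
  expect_equal(regc$r_squared, 0)

  set.seed(8)
  xr <- rnorm(50); yr <- rnorm(50)
  X <- cbind(1, xr)
  beta <- solve(t(X) %*% X, t(X) %*% yr)
  rr <- simple_regression(xr, yr)
  expect_equal(c(rr$intercept, rr$slope), as.numeric(beta), tolerance = 1e-10)
  expect_error(simple_regression(rep(1, 10), rnorm(10)), "constant")
})

test_that("experiment model specifications enumerate the study structures", {
  s1 <- build_exp1_specs()
  expect_length(s1, 6)
  expect_true(all(vapply(s1, function(s)
    identical(s$random_intercepts, c("device", "device:root")), logical(1))))

  s2 <- build_exp2_specs()
  expect_equal(s2$model1$fixed_terms, "growth_rate")
  # Model 2: intercept + growth + 2 treatment + 1 period + 2 interaction = 7
  rec <- simulate_exp2_records(experiment_config(), seed = 3)
  f2 <- fit_lmm(rec, s2$model2)
  expect_equal(nrow(f2$estimates), 7)

  # all specs validate against the synthetic tables
  e1 <- simulate_experiment1(experiment_config(), seed = 3)
  for (sp in s1) expect_s3_class(fit_lmm(e1, sp), "model_fit")
  for (sp in s2) expect_s3_class(fit_lmm(rec, sp), "model_fit")
})

test_that("fixed-effect bias shrinks as the number of roots grows", {
  slope_bias <- function(n_roots, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- experiment_config(roots_per_treatment = n_roots, hours = 24, seed = s)
      rec <- simulate_exp2_records(cfg)
      f <- fit_lmm(rec, build_exp2_specs()$model2)
      f$estimates$estimate[f$estimates$term == "growth_rate"] + 2.74e-3
    }, numeric(1)))
  }
  b_small <- abs(slope_bias(2, 1:15))
  b_large <- abs(slope_bias(8, 1:15))
  expect_lt(b_large, 5e-5)
  expect_lt(b_large, b_small + 5e-5)
})

test_that("log transform and missing-column validation behave", {
  e1 <- simulate_experiment1(experiment_config(), seed = 4)
  sp <- model_spec("long_hypoxic_length", "treatment",
                   c("device", "device:root"), transform = "log")
  f <- fit_lmm(e1, sp)
  expect_s3_class(f, "model_fit")
  expect_error(fit_lmm(e1, model_spec("nope", "treatment")), "lacks columns")
  expect_error(fit_lmm(e1[e1$device == "device01", ],
                       model_spec("long_hypoxic_length", "treatment", "device")),
               "fewer than 2")
})
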