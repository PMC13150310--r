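# Seeded synthetic-data generators: parametric ground-truth O2 fields with
# analytic minima and threshold crossings, two-channel optode renderings,
# timelapse tracks with known growth/depletion coupling, and multi-device
# metric tables with the nested random-effect structure the mixed-effects
# stage assumes.

#' Configuration of a synthetic root-tip oxygen scene
#'
#' The ground-truth field is a separable Gaussian depletion plume on a
#' straight root axis:
#' `O2(s, d) = O2_bg - [dO2_tip * exp(-(s - s_min)^2 / (2 sigma_L^2)) +
#' dO2_mat / (1 + exp(-(s - rise_pos) / rise_width))] * exp(-d^2 / (2 sigma_T^2))`
#' with `s` the arc position along the root axis and `d` the distance from
#' it (micrometres). The tip term produces the depletion minimum behind the
#' apex; the logistic term the depressed mature-root plateau. A parametric
#' field (rather than a reaction-diffusion solution) keeps minima and
#' threshold crossings analytic, giving exact test oracles.
#'
#' Defaults emulate the study conditions: background at air saturation
#' (9.2 mg l-1), a suboxic tip minimum, a mature plateau near 4.4 mg l-1,
#' and hypoxic/suboxic longitudinal extents of order 1300/300 um.
#'
#' @param nx,ny Image size in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param axis_y Row (0-based pixel units) of the horizontal root axis.
#' @param s_min Arc position of the tip depletion centre, um.
#' @param O2_bg Background O2, mg l-1.
#' @param dO2_tip Tip depletion depth, mg l-1.
#' @param dO2_mat Mature plateau depression, mg l-1.
#' @param sigma_L,sigma_T Longitudinal/transverse plume scales, um.
#' @param rise_pos,rise_width Centre and width of the smooth rise to the
#'   mature plateau, um.
#' @param cap_pos,hair_pos Landmark arc positions, um.
#' @param fit `calibration_fit` used to invert the field into channels.
#' @param ref_level Constant reference-channel intensity (counts).
#' @param noise_sd Multiplicative Gaussian noise SD per channel.
#' @param seed Integer seed recorded with the scene.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(nx = 5000, ny = 700, pixel_size = 1.6,
                         axis_y = (ny - 1) / 2,
                         s_min = 700, O2_bg = 9.2, dO2_tip = 9.12,
                         dO2_mat = 4.8, sigma_L = 950, sigma_T = 260,
                         rise_pos = s_min + 3000, rise_width = 300,
                         cap_pos = s_min - 250, hair_pos = cap_pos + 7000,
                         fit = fit_two_point(0.5, 1.5, 9.2, 0),
                         ref_level = 20000, noise_sd = 0.01, seed = 1L) {
  stopifnot(sigma_L > 0, sigma_T > 0, rise_width > 0, pixel_size > 0)
  cfg <- structure(list(nx = nx, ny = ny, pixel_size = pixel_size,
                        axis_y = axis_y, s_min = s_min, O2_bg = O2_bg,
                        dO2_tip = dO2_tip, dO2_mat = dO2_mat,
                        sigma_L = sigma_L, sigma_T = sigma_T,
                        rise_pos = rise_pos, rise_width = rise_width,
                        cap_pos = cap_pos, hair_pos = hair_pos,
                        fit = fit, ref_level = ref_level,
                        noise_sd = noise_sd, seed = as.integer(seed)),
                   class = "scene_config")
  mn <- scene_min(cfg)
  if (mn$value <= fit$C)
    stop("config error: field minimum ", signif(mn$value, 4),
         " does not exceed the calibration offset C = ", signif(fit$C, 4),
         "; the field would not be invertible")
  cfg
}

#' Ground-truth O2 value of a scene at axis coordinates
#'
#' @param cfg A `scene_config`.
#' @param s Arc position(s) along the root axis, um.
#' @param d Distance(s) from the axis, um.
#' @return O2 in mg l-1.
#' @export
scene_truth <- function(cfg, s, d) {
  depl <- cfg$dO2_tip * exp(-(s - cfg$s_min)^2 / (2 * cfg$sigma_L^2)) +
    cfg$dO2_mat / (1 + exp(-(s - cfg$rise_pos) / cfg$rise_width))
  cfg$O2_bg - depl * exp(-d^2 / (2 * cfg$sigma_T^2))
}

#' Analytic minimum of a scene's O2 field
#'
#' The minimum lies on the axis (d = 0) where the known depletion
#' expression is maximal; the 1-D maximization of that closed form is done
#' to machine precision.
#'
#' @param cfg A `scene_config`.
#' @return List: `value` (mg l-1), `s` (um), `d` (0).
#' @export
scene_min <- function(cfg) {
  f <- function(s) scene_truth(cfg, s, 0)
  span <- 4 * cfg$sigma_L
  opt <- stats::optimize(f, c(max(0, cfg$s_min - span), cfg$s_min + span),
                         tol = 1e-10)
  list(value = opt$objective, s = opt$minimum, d = 0)
}

#' Analytic threshold-crossing lengths of a scene
#'
#' Longitudinal: arc length on the axis where the closed-form field is
#' below `threshold`, with crossing points found by root-finding on the
#' known expression. Transverse: at the field minimum the transverse cut is
#' Gaussian, so the sub-threshold half-width is
#' `sigma_T * sqrt(2 * log(D / (O2_bg - threshold)))` with `D` the total
#' axis depletion there.
#'
#' @param cfg A `scene_config`.
#' @param threshold O2 threshold, mg l-1.
#' @return List: `longitudinal_length`, `transverse_length` (um), and the
#'   longitudinal crossing positions `s_lo`, `s_hi`.
#' @export
scene_crossings <- function(cfg, threshold) {
  mn <- scene_min(cfg)
  if (mn$value >= threshold)
    return(list(longitudinal_length = 0, transverse_length = 0,
                s_lo = NA_real_, s_hi = NA_real_))
  g <- function(s) scene_truth(cfg, s, 0) - threshold
  lo_brack <- max(0, cfg$s_min - 6 * cfg$sigma_L)
  s_lo <- stats::uniroot(g, c(lo_brack, mn$s), tol = 1e-10)$root
  # upper crossing: field rises after the tip dip; the mature plateau stays
  # above both default thresholds, so a single contiguous region results
  hi_brack <- mn$s
  step <- cfg$sigma_L / 4
  while (g(hi_brack) < 0) hi_brack <- hi_brack + step
  s_hi <- stats::uniroot(g, c(mn$s, hi_brack), tol = 1e-10)$root
  D <- cfg$O2_bg - mn$value
  trans <- 2 * cfg$sigma_T * sqrt(2 * log(D / (cfg$O2_bg - threshold)))
  list(longitudinal_length = s_hi - s_lo, transverse_length = trans,
       s_lo = s_lo, s_hi = s_hi)
}

#' Render a scene's ground-truth oxygen map
#'
#' Evaluates the closed-form field at every pixel centre (0-based
#' pixel-center convention; `s = x * pixel_size`,
#' `d = (y - axis_y) * pixel_size`).
#'
#' @param cfg A `scene_config`.
#' @return An `o2_map`.
#' @export
o2_field <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  s <- (seq_len(cfg$nx) - 1) * cfg$pixel_size
  d <- (seq_len(cfg$ny) - 1 - cfg$axis_y) * cfg$pixel_size
  depl_s <- cfg$dO2_tip * exp(-(s - cfg$s_min)^2 / (2 * cfg$sigma_L^2)) +
    cfg$dO2_mat / (1 + exp(-(s - cfg$rise_pos) / cfg$rise_width))
  gT <- exp(-d^2 / (2 * cfg$sigma_T^2))
  pixels <- cfg$O2_bg - outer(gT, depl_s)   # rows = y, cols = x
  o2_map(pixels, cfg$pixel_size, provenance = "synthetic scene")
}

#' Render sensor/reference channel images from a truth map
#'
#' Inverts the calibration, `R = -log((O2 - C) / A) / 2`, sets the
#' reference channel to a constant plateau and the sensor to
#' `reference * R`, then applies independent multiplicative Gaussian noise
#' per channel. A noiseless rendering (`noise_sd = 0`) is exactly inverted
#' by [compute_ratio()] + [ratio_to_o2()].
#'
#' @param truth An `o2_map` with all values above the calibration offset C.
#' @param cfg A `scene_config` (supplies `fit`, `ref_level`, `noise_sd`).
#' @param seed Seed for the channel noise (default: the scene's).
#' @return List with `sensor` and `reference` `channel_image`s.
#' @export
render_channels <- function(truth, cfg, seed = cfg$seed) {
  stopifnot(inherits(truth, "o2_map"), inherits(cfg, "scene_config"))
  fit <- cfg$fit
  if (any(truth$pixels[truth$mask] <= fit$C))
    stop("invertibility error: O2 <= C somewhere in the field")
  R <- -0.5 * log((truth$pixels - fit$C) / fit$A)
  if (any(R[truth$mask] < 0))
    stop("invertibility error: O2 above the calibration range (R < 0)")
  ref <- matrix(cfg$ref_level, nrow(truth$pixels), ncol(truth$pixels))
  sen <- ref * R
  if (cfg$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sen <- sen * (1 + cfg$noise_sd * stats::rnorm(length(sen)))
    ref <- ref * (1 + cfg$noise_sd * stats::rnorm(length(ref)))
    sen <- pmax(sen, 0)
    ref <- pmax(ref, 0)
  }
  list(sensor = channel_image(sen, truth$pixel_size, "sensor"),
       reference = channel_image(ref, truth$pixel_size, "reference"))
}

#' Configuration of a synthetic experiment
#'
#' Holds the treatment structure, effect sizes and variance components used
#' by [simulate_exp2_records()], [simulate_timelapse()] and
#' [simulate_experiment1()]. Timelapse effect defaults are the study's
#' fitted Model 2 coefficients (intercept 3.58 mg l-1; growth-rate slope
#' -2.74e-3 mg l-1 per um/h; treatment offsets -6.42e-3 and 1.92; dark
#' offset 1.46; interaction offsets -0.884 and -1.99) with a mean growth
#' rate of 621 um/h. The root-intercept SD (0.59) and residual SD (0.74)
#' were derived before any fitting, by closed-form variance arithmetic, so
#' that the generated variance partition approximates the study's Model 2
#' R2 pair (0.49/0.69) at growth-rate SD 200 um/h.
#'
#' @param treatments Treatment labels (reference first).
#' @param roots_per_treatment Roots per treatment (timelapse).
#' @param hours Hourly timepoints per root beyond the first image.
#' @param intercept,growth_slope,treat_effects,dark_effect,interaction_dark
#'   Fixed-effect generating values for the timelapse O2 minimum.
#' @param root_sd,resid_sd Random-intercept and residual SDs, mg l-1.
#' @param rate_mean,rate_sd Growth-rate process mean and SD, um/h.
#' @param schedule A `light_schedule`.
#' @param devices_per_treatment,roots_per_device,days Oxygen-gradient
#'   experiment design (defaults reproduce 36 roots in 10 devices across 3
#'   treatments, imaged daily for 7 days).
#' @param seed Integer seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(treatments = c("Sterile", "P_protegens", "SoilCommunity"),
                              roots_per_treatment = 3, hours = 48,
                              intercept = 3.58, growth_slope = -2.74e-3,
                              treat_effects = c(Sterile = 0,
                                                P_protegens = -6.42e-3,
                                                SoilCommunity = 1.92),
                              dark_effect = 1.46,
                              interaction_dark = c(Sterile = 0,
                                                   P_protegens = -0.884,
                                                   SoilCommunity = -1.99),
                              root_sd = 0.59, resid_sd = 0.74,
                              rate_mean = 621, rate_sd = 200,
                              schedule = light_schedule(),
                              devices_per_treatment = c(Sterile = 3,
                                                        P_protegens = 3,
                                                        SoilCommunity = 4),
                              roots_per_device = c(Sterile = 4,
                                                   P_protegens = 4,
                                                   SoilCommunity = 3),
                              days = 7, seed = 1L) {
  stopifnot(root_sd >= 0, resid_sd >= 0, rate_sd >= 0,
            roots_per_treatment >= 1, all(roots_per_device >= 1))
  structure(list(treatments = treatments,
                 roots_per_treatment = roots_per_treatment, hours = hours,
                 intercept = intercept, growth_slope = growth_slope,
                 treat_effects = treat_effects, dark_effect = dark_effect,
                 interaction_dark = interaction_dark,
                 root_sd = root_sd, resid_sd = resid_sd,
                 rate_mean = rate_mean, rate_sd = rate_sd,
                 schedule = schedule,
                 devices_per_treatment = devices_per_treatment,
                 roots_per_device = roots_per_device,
                 days = days, seed = as.integer(seed)),
            class = "experiment_config")
}

# true mean O2 minimum for given covariates under the generating model
.exp2_linpred <- function(cfg, treatment, rate, period) {
  cfg$intercept + cfg$growth_slope * rate +
    cfg$treat_effects[treatment] +
    ifelse(period == "dark",
           cfg$dark_effect + cfg$interaction_dark[treatment], 0)
}

# positive hourly growth rates (normal truncated at a small floor)
.draw_rates <- function(n, mean, sd) {
  r <- stats::rnorm(n, mean, sd)
  pmax(r, 1)
}

#' Simulate a timelapse track of a growing root tip
#'
#' Draws hourly interval growth rates from the configured process, advances
#' the cap along a straight line, and attaches a longitudinal profile per
#' timepoint whose windowed O2 minimum equals the generating model's value
#' exactly: `o2_min = intercept + slope * instantaneous_rate + treatment +
#' period effects + root intercept + noise`. Profiles are Gaussian dips
#' scaled so the analysis window recovers the target by construction
#' (the window machinery is linear in profile values).
#'
#' @param cfg An `experiment_config`.
#' @param treatment Treatment label.
#' @param root_id Root identifier.
#' @param hours Number of hourly intervals (timepoints = hours + 1).
#' @param seed Seed (default: the config's).
#' @param noise Logical; `FALSE` suppresses the root intercept and residual
#'   noise (ground truth only).
#' @param profile_spacing Profile sample spacing, um.
#' @return List: `track` (a `timelapse_track`) and `truth` (data.frame of
#'   generating values per timepoint).
#' @export
simulate_timelapse <- function(cfg, treatment = cfg$treatments[1L],
                               root_id = "root1", hours = cfg$hours,
                               seed = cfg$seed, noise = TRUE,
                               profile_spacing = 5) {
  stopifnot(inherits(cfg, "experiment_config"), hours >= 2)
  if (!is.null(seed)) set.seed(seed)
  times <- 0:hours
  n <- length(times)
  ivr <- if (noise) .draw_rates(n - 1L, cfg$rate_mean, cfg$rate_sd)
         else rep(cfg$rate_mean, n - 1L)
  caps <- cbind(c(0, cumsum(ivr * diff(times))), 0)
  inst <- c(ivr[1L], (utils::head(ivr, -1) + utils::tail(ivr, -1)) / 2,
            ivr[length(ivr)])
  if (length(ivr) == 1L) inst <- c(ivr, ivr)
  period <- assign_period(times, cfg$schedule)
  b_root <- if (noise) stats::rnorm(1L, 0, cfg$root_sd) else 0
  eps <- if (noise) stats::rnorm(n, 0, cfg$resid_sd) else numeric(n)
  target <- .exp2_linpred(cfg, treatment, inst, period) + b_root + eps
  # profile template: Gaussian dip on a 3000-um axis, dip centred at 800 um
  pos <- seq(0, 3000, by = profile_spacing)
  gdip <- exp(-(pos - 800)^2 / (2 * 150^2))
  bg <- 9.2
  tmpl <- o2_profile(pos, bg - gdip)
  M <- bg - o2_minimum(tmpl, 500)   # max window mean of the unit dip
  profiles <- lapply(seq_len(n), function(i) {
    k <- (bg - target[i]) / M
    o2_profile(pos, bg - k * gdip)
  })
  track <- timelapse_track(times, caps, profiles, treatment, root_id,
                           cfg$schedule)
  truth <- data.frame(time_h = times, interval_rate = c(ivr, NA),
                      instantaneous_rate = inst, period = period,
                      true_o2_min = target, root_intercept = b_root)
  list(track = track, truth = truth)
}

#' Simulate the timelapse experiment's tidy record table
#'
#' Fast generator of the growth-records table (no profiles rendered):
#' instantaneous rates from the configured process and O2 minima from the
#' generating fixed effects plus a per-root random intercept and residual
#' noise, for all treatments and roots.
#'
#' @param cfg An `experiment_config`.
#' @param seed Seed (default: the config's).
#' @return data.frame with `root_id`, `treatment`, `time_h`, `growth_rate`,
#'   `o2_min`, `period`; generating values attached as attribute `truth`.
#' @export
simulate_exp2_records <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (tr in cfg$treatments) {
    for (r in seq_len(cfg$roots_per_treatment)) {
      times <- 0:cfg$hours
      n <- length(times)
      ivr <- .draw_rates(n - 1L, cfg$rate_mean, cfg$rate_sd)
      inst <- c(ivr[1L], (utils::head(ivr, -1) + utils::tail(ivr, -1)) / 2,
                ivr[length(ivr)])
      period <- assign_period(times, cfg$schedule)
      b <- stats::rnorm(1L, 0, cfg$root_sd)
      y <- .exp2_linpred(cfg, tr, inst, period) + b +
        stats::rnorm(n, 0, cfg$resid_sd)
      out[[length(out) + 1L]] <-
        data.frame(root_id = paste0(tr, "_root", r), treatment = tr,
                   time_h = times, growth_rate = inst, o2_min = y,
                   period = period, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- list(intercept = cfg$intercept,
                             growth_slope = cfg$growth_slope,
                             treat_effects = cfg$treat_effects,
                             dark_effect = cfg$dark_effect,
                             interaction_dark = cfg$interaction_dark,
                             root_sd = cfg$root_sd, resid_sd = cfg$resid_sd)
  res
}

#' Default per-metric generating values for the oxygen-gradient experiment
#'
#' Treatment means at the study scale: mature-zone O2 4.4 mg l-1 in all
#' treatments; longitudinal hypoxic length 1285 um; longitudinal suboxic
#' lengths 139/557/278 um for Sterile, P. protegens and Soil Community;
#' transverse hypoxic/suboxic lengths 290/74 um; transverse decrease
#' 8.1 mg l-1. SDs are fractions of each metric's grand mean (device 10%,
#' root 10%, residual 15%).
#'
#' @return List with `means` (metric x treatment matrix) and `sds`
#'   (data.frame of device/root/residual SDs per metric).
#' @export
exp1_metric_defaults <- function() {
  metrics <- c("long_mean_mature_o2", "long_hypoxic_length",
               "long_suboxic_length", "trans_hypoxic_length",
               "trans_suboxic_length", "trans_max_decrease")
  treatments <- c("Sterile", "P_protegens", "SoilCommunity")
  means <- rbind(long_mean_mature_o2 = c(4.4, 4.4, 4.4),
                 long_hypoxic_length = c(1285, 1285, 1285),
                 long_suboxic_length = c(139, 557, 278),
                 trans_hypoxic_length = c(290, 290, 290),
                 trans_suboxic_length = c(74, 74, 74),
                 trans_max_decrease = c(8.1, 8.1, 8.1))
  colnames(means) <- treatments
  grand <- rowMeans(means)
  sds <- data.frame(metric = metrics, device_sd = 0.10 * grand,
                    root_sd = 0.10 * grand, resid_sd = 0.15 * grand,
                    row.names = NULL)
  list(means = means, sds = sds)
}

#' Simulate the oxygen-gradient experiment's tidy metric table
#'
#' Per root-day rows for all six response metrics, drawn as treatment mean
#' + device intercept + root intercept + residual noise, with the nested
#' design (roots within devices within treatments) of the gradient
#' experiment: by default 36 roots in 10 devices across 3 treatments,
#' imaged daily for 7 days.
#'
#' @param cfg An `experiment_config`.
#' @param seed Seed (default: the config's).
#' @param defaults Metric means/SDs as from [exp1_metric_defaults()].
#' @param sd_scale Multiplier on all SDs (0 gives noiseless tables).
#' @return data.frame with `device`, `root`, `treatment`, `day` and one
#'   column per metric; generating values attached as attribute `truth`.
#' @export
simulate_experiment1 <- function(cfg, seed = cfg$seed,
                                 defaults = exp1_metric_defaults(),
                                 sd_scale = 1) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(seed)) set.seed(seed)
  means <- defaults$means; sds <- defaults$sds
  metrics <- rownames(means)
  rows <- list()
  dev_counter <- 0L
  for (tr in cfg$treatments) {
    for (dv in seq_len(cfg$devices_per_treatment[[tr]])) {
      dev_counter <- dev_counter + 1L
      device <- sprintf("device%02d", dev_counter)
      b_dev <- stats::rnorm(length(metrics), 0, sd_scale * sds$device_sd)
      for (rt in seq_len(cfg$roots_per_device[[tr]])) {
        root <- sprintf("%s_r%d", device, rt)
        b_root <- stats::rnorm(length(metrics), 0, sd_scale * sds$root_sd)
        for (day in seq_len(cfg$days)) {
          eps <- stats::rnorm(length(metrics), 0, sd_scale * sds$resid_sd)
          vals <- means[, tr] + b_dev + b_root + eps
          row <- data.frame(device = device, root = root, treatment = tr,
                            day = day, stringsAsFactors = FALSE)
          row[metrics] <- as.list(vals)
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "truth") <- list(means = means, sds = sds, sd_scale = sd_scale)
  res
}
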