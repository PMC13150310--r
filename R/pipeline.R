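# End-to-end orchestration: synthetic scene -> calibration -> O2 maps ->
# profile/timelapse metrics -> microsite geometry -> mixed models, with a
# JSON run manifest recording the seed, config hash and per-artifact
# checksums.

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "calibrate", "o2map", "profile", "timelapse",
#'   "geometry", "stats")`. Later stages read the files earlier stages
#'   wrote, so disabling a stage requires its inputs to exist already.
#' @param scene A `scene_config` (default: a compact scene with the same
#'   field shape as the full-size default).
#' @param experiment An `experiment_config`.
#' @param thresholds A `threshold_config`.
#' @param window O2-minimum window, micrometres.
#' @param n_calibration Calibration image pairs per endpoint.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "calibrate", "o2map", "profile",
                                  "timelapse", "geometry", "stats"),
                       scene = NULL, experiment = NULL,
                       thresholds = threshold_config(), window = 500,
                       n_calibration = 10L) {
  if (is.null(scene))
    scene <- scene_config(nx = 1500, ny = 400, pixel_size = 2, s_min = 500,
                          sigma_L = 300, sigma_T = 120, cap_pos = 250,
                          hair_pos = 2750, rise_pos = 1500, rise_width = 100,
                          seed = seed)
  if (is.null(experiment))
    experiment <- experiment_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 scene = scene, experiment = experiment,
                 thresholds = thresholds, window = window,
                 n_calibration = as.integer(n_calibration)),
            class = "run_config")
}

# stable hash of a run configuration (md5 of its deparsed form)
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.full_precision_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the pipeline end-to-end
#'
#' Executes the toggled stages in order, writing every intermediate as a
#' plain-text or TIFF artifact under `out_dir`, and returns (and writes) a
#' manifest recording the seed, the configuration hash and an md5 checksum
#' per artifact. Reruns with the same configuration and seed reproduce
#' byte-identical CSV outputs. Any stage failure aborts with an error naming
#' the stage.
#'
#' @param cfg A `run_config`.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    truth = file.path(cfg$out_dir, "scene_truth.txt"),
    sensor = file.path(cfg$out_dir, "scene_sensor.tif"),
    reference = file.path(cfg$out_dir, "scene_reference.tif"),
    cal_dir = file.path(cfg$out_dir, "calibration"),
    fit = file.path(cfg$out_dir, "calibration_fit.dcf"),
    o2map = file.path(cfg$out_dir, "o2_map.txt"),
    profile_metrics = file.path(cfg$out_dir, "profile_metrics.csv"),
    records = file.path(cfg$out_dir, "growth_records.csv"),
    exp1 = file.path(cfg$out_dir, "exp1_metrics.csv"),
    geometry = file.path(cfg$out_dir, "geometry.json"),
    fits = file.path(cfg$out_dir, "model_fits.csv"),
    manifest = file.path(cfg$out_dir, "manifest.json"))
  artifacts <- character()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  scn <- cfg$scene

  if ("simulate" %in% cfg$stages) run_stage("simulate", {
    truth <- o2_field(scn)
    write_text_image(truth$pixels, paths$truth)
    ch <- render_channels(truth, scn, seed = cfg$seed)
    # counts for 16-bit TIFF: reference plateau ~20000, sensor = ref * R
    write_channel_tiff(ch$sensor, paths$sensor)
    write_channel_tiff(ch$reference, paths$reference)
    dir.create(paths$cal_dir, showWarnings = FALSE)
    for (ep in c("air", "anoxic")) {
      o2v <- if (ep == "air") scn$fit$O2_air else scn$fit$O2_anoxic
      flat <- o2_map(matrix(o2v, 64, 64), scn$pixel_size)
      for (k in seq_len(cfg$n_calibration)) {
        chk <- render_channels(flat, scn, seed = cfg$seed + 1000L +
                                 k + ifelse(ep == "air", 0L, 500L))
        write_channel_tiff(chk$sensor,
                           file.path(paths$cal_dir, sprintf("%s_%02d_sensor.tif", ep, k)))
        write_channel_tiff(chk$reference,
                           file.path(paths$cal_dir, sprintf("%s_%02d_reference.tif", ep, k)))
      }
    }
    exp1 <- simulate_experiment1(cfg$experiment, seed = cfg$seed + 1L)
    .full_precision_csv(exp1, paths$exp1)
    rec <- simulate_exp2_records(cfg$experiment, seed = cfg$seed + 2L)
    .full_precision_csv(rec, paths$records)
    artifacts <- c(artifacts, paths$truth, paths$sensor, paths$reference,
                    paths$exp1, paths$records,
                    list.files(paths$cal_dir, full.names = TRUE))
  })

  if ("calibrate" %in% cfg$stages) run_stage("calibrate", {
    read_pairs <- function(ep) {
      lapply(seq_len(cfg$n_calibration), function(k) list(
        read_channel_tiff(file.path(paths$cal_dir, sprintf("%s_%02d_sensor.tif", ep, k)),
                          scn$pixel_size, "sensor"),
        read_channel_tiff(file.path(paths$cal_dir, sprintf("%s_%02d_reference.tif", ep, k)),
                          scn$pixel_size, "reference")))
    }
    fit <- fit_two_point(mean_ratio(read_pairs("air")),
                         mean_ratio(read_pairs("anoxic")),
                         scn$fit$O2_air, scn$fit$O2_anoxic)
    write_calibration(fit, paths$fit)
    artifacts <- c(artifacts, paths$fit)
  })

  if ("o2map" %in% cfg$stages) run_stage("o2map", {
    fit <- read_calibration(paths$fit)
    sen <- read_channel_tiff(paths$sensor, scn$pixel_size, "sensor")
    ref <- read_channel_tiff(paths$reference, scn$pixel_size, "reference")
    map <- ratio_to_o2(compute_ratio(sen, ref), fit)
    write_text_image(map$pixels, paths$o2map)
    artifacts <- c(artifacts, paths$o2map)
  })

  if ("profile" %in% cfg$stages) run_stage("profile", {
    map <- o2_map(read_text_image(paths$o2map), scn$pixel_size)
    yax <- scn$axis_y
    long <- sample_profile(map,
                           polyline(rbind(c(0, yax), c(scn$nx - 1, yax)),
                                    "longitudinal"),
                           landmarks = list(cap_pos = scn$cap_pos,
                                            hair_pos = scn$hair_pos))
    lm_metrics <- longitudinal_metrics(long, cfg$thresholds)
    xmin_px <- scene_min(scn)$s / scn$pixel_size
    trans <- sample_profile(map,
                            polyline(rbind(c(xmin_px, 0), c(xmin_px, scn$ny - 1)),
                                     "transverse"))
    tr_metrics <- transverse_metrics(trans, cfg$thresholds)
    .full_precision_csv(data.frame(
      long_mean_mature_o2 = lm_metrics$mean_mature_o2,
      long_hypoxic_length = lm_metrics$hypoxic_length,
      long_suboxic_length = lm_metrics$suboxic_length,
      trans_hypoxic_length = tr_metrics$hypoxic_length,
      trans_suboxic_length = tr_metrics$suboxic_length,
      trans_max_decrease = tr_metrics$max_decrease), paths$profile_metrics)
    artifacts <- c(artifacts, paths$profile_metrics)
  })

  if ("timelapse" %in% cfg$stages) run_stage("timelapse", {
    sim <- simulate_timelapse(cfg$experiment, seed = cfg$seed + 3L)
    rec <- build_growth_records(sim$track, cfg$window)
    reg <- simple_regression(rec$growth_rate, rec$o2_min)
    .full_precision_csv(cbind(rec, fit_slope = reg$slope,
                              fit_intercept = reg$intercept),
                        file.path(cfg$out_dir, "timelapse_records.csv"))
    artifacts <- c(artifacts, file.path(cfg$out_dir, "timelapse_records.csv"))
  })

  if ("geometry" %in% cfg$stages) run_stage("geometry", {
    pm <- utils::read.csv(paths$profile_metrics)
    geo <- list(
      suboxic_volume_um3 = suboxic_volume(pm$long_suboxic_length,
                                          pm$trans_suboxic_length),
      exposure_time_min = exposure_time(pm$long_suboxic_length,
                                        cfg$experiment$rate_mean))
    jsonlite::write_json(geo, paths$geometry, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, paths$geometry)
  })

  if ("stats" %in% cfg$stages) run_stage("stats", {
    rec <- utils::read.csv(paths$records)
    exp1 <- utils::read.csv(paths$exp1)
    fits <- c(lapply(build_exp2_specs(), function(sp) fit_lmm(rec, sp)),
              lapply(build_exp1_specs(), function(sp) fit_lmm(exp1, sp)))
    .full_precision_csv(fit_report(fits), paths$fits)
    artifacts <- c(artifacts, paths$fits)
  })

  artifacts <- unique(artifacts[file.exists(artifacts)])
  manifest <- list(seed = cfg$seed, config_hash = .config_hash(cfg),
                   stages = cfg$stages,
                   artifacts = lapply(artifacts, function(p) list(
                     path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(manifest)
}
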