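# rhizO2

Quantification of rhizosphere anoxic microsites from ratiometric
planar-optode oxygen images.

## Scientific problem

Respiring root tips can deplete dissolved O2 in their immediate
surroundings faster than diffusion resupplies it, creating micro-scale,
short-lived **anoxic microsites** that shift the local microbiome toward
anaerobic metabolism. Transparent planar O2 optodes in microfluidic
devices image this depletion: a luminescent sensor layer is photographed
in two channels, and the sensor/reference ratio `R` reports O2 through a
two-point exponential calibration

    O2(R) = A * exp(-2 R) + C        [mg l-1]

with `A`, `C` fixed by air-saturated (9.2 mg l-1) and anoxic (0 mg l-1)
water. `rhizO2` covers the whole measurement chain:

* **Calibration and mapping** — `fit_two_point()`, `compute_ratio()`,
  `ratio_to_o2()`: channel images to calibrated O2 maps (no clamping;
  zero-reference pixels are masked).
* **Profiles** — `sample_profile()` along polylines (bilinear),
  `normalize_longitudinal()` between root-cap and root-hair landmarks,
  sub-sample-resolution `threshold_length()` below the hypoxic
  (1.92 mg l-1) and suboxic (0.16 mg l-1) thresholds,
  `longitudinal_metrics()` / `transverse_metrics()` / `average_profiles()`.
* **Timelapse** — growth rates from tip tracks
  (`interval_growth_rates()`, `instantaneous_rate()`), exact windowed O2
  minima (`o2_minimum()`), light/dark assignment (`assign_period()`),
  `build_growth_records()`.
* **Geometry** — `suboxic_volume()` (cylinder of revolution) and
  `exposure_time()` (minutes a fixed point spends suboxic as the tip
  grows past).
* **Mixed models** — `fit_lmm()` (REML via lme4) with nested random
  intercepts, variance-partition marginal/conditional R2, and the two
  study designs prebuilt (`build_exp1_specs()`, `build_exp2_specs()`).
* **Synthetic data** — seeded parametric scene with analytic minima and
  threshold crossings (`scene_config()`, `scene_min()`,
  `scene_crossings()`, `render_channels()`), timelapse and experiment
  generators (`simulate_timelapse()`, `simulate_exp2_records()`,
  `simulate_experiment1()`).
* **Pipeline** — `run_pipeline()`: simulate → calibrate → map → profile
  → timelapse → geometry → stats, with a checksummed `manifest.json` and
  byte-reproducible CSVs; CLI wrapper in `inst/scripts/rhizO2-pipeline.R`.

See the vignette (`vignettes/anoxic-microsites.Rmd`) for the model
details, algorithmic choices and limitations.

## Worked example

```r
library(rhizO2)

## calibration from two endpoint ratios
fit <- fit_two_point(R_air = 0.5, R_anoxic = 1.5)
fit
#> Two-point optode calibration: O2 = A * exp(-2 R) + C
#>   A = 28.9224 mg/l, C = -1.43996 mg/l
#>   endpoints: R_air = 0.5 (9.2 mg/l), R_anoxic = 1.5 (0 mg/l)

## synthetic scene -> noisy channels -> calibrated map -> profile metrics
cfg <- scene_config(nx = 1500, ny = 401, pixel_size = 2, s_min = 500,
                    sigma_L = 200, sigma_T = 100, cap_pos = 250,
                    hair_pos = 2750, rise_pos = 2500, rise_width = 100,
                    noise_sd = 0.01, seed = 42)
ch  <- render_channels(o2_field(cfg), cfg)
map <- ratio_to_o2(compute_ratio(ch$sensor, ch$reference), cfg$fit)
long <- sample_profile(map,
                       polyline(rbind(c(0, cfg$axis_y),
                                      c(cfg$nx - 1, cfg$axis_y)),
                                "longitudinal"),
                       landmarks = list(cap_pos = cfg$cap_pos,
                                        hair_pos = cfg$hair_pos))
longitudinal_metrics(long)[c("mean_mature_o2", "hypoxic_length", "suboxic_length")]
#> $mean_mature_o2
#> [1] 7.222858
#> $hypoxic_length
#> [1] 266.6571
#> $suboxic_length
#> [1] 37.22572

## microsite geometry at the study scale
suboxic_volume(longitudinal_length = 332, transverse_length = 74)
#> [1] 1427879
exposure_time(suboxic_length = 332, growth_rate = 621)
#> [1] 32.07729

## mixed model on a simulated timelapse experiment
rec <- simulate_exp2_records(experiment_config(), seed = 42)
fit_lmm(rec, build_exp2_specs()$model2)
#> Linear mixed model: o2_min ~ growth_rate + treatment + period + treatment:period
#>   random intercepts: treatment:root_id
#>   n = 441, R2m = 0.491, R2c = 0.598
#>                               term  estimate       se        p stars
#>                        (Intercept)  2.965000 0.286200 1.28e-22   ***
#>                        growth_rate -0.002445 0.000258 1.72e-19   ***
#>               treatmentP_protegens  0.747000 0.327500 2.30e-02     *
#>             treatmentSoilCommunity  2.067000 0.327500 6.81e-10   ***
#>                         perioddark  1.453000 0.121000 6.81e-29   ***
#>    treatmentP_protegens:perioddark -0.643600 0.169300 1.65e-04   ***
#>  treatmentSoilCommunity:perioddark -2.063000 0.169300 1.40e-29   ***
```

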