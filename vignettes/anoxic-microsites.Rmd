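---
title: "Quantifying rhizosphere anoxic microsites from planar-optode images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rhizosphere anoxic microsites from planar-optode images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizO2)
```

# Scientific setting

Growing root tips respire strongly and can locally deplete dissolved
oxygen in the surrounding (rhizosphere) medium faster than diffusion
replenishes it, producing transient *anoxic microsites* — micro-scale,
short-lived volumes where O2 falls low enough to switch microbial
metabolism to anaerobic pathways. Transparent planar O2 optodes imaged
through a microfluidic device resolve these microsites in space and time:
a luminescent sensor layer is imaged in two channels and the channel ratio
reports O2.

`rhizO2` implements the full quantification chain:

1. ratiometric two-point calibration and conversion of channel images to
   O2 maps (`fit_two_point`, `compute_ratio`, `ratio_to_o2`);
2. profile extraction along polylines, longitudinal normalization between
   root landmarks, and threshold-length metrics (`sample_profile`,
   `normalize_longitudinal`, `threshold_length`, `longitudinal_metrics`,
   `transverse_metrics`);
3. timelapse analysis: growth rates from tip tracks, windowed O2 minima,
   and light/dark period assignment (`interval_growth_rates`,
   `o2_minimum`, `assign_period`, `build_growth_records`);
4. microsite geometry: suboxic volume and microbial exposure time
   (`suboxic_volume`, `exposure_time`);
5. linear mixed-effects models with nested random intercepts and a
   variance-partition R2 (`fit_lmm`, `build_exp1_specs`,
   `build_exp2_specs`, `r2_variance_partition`);
6. seeded synthetic-data generators and an end-to-end pipeline
   (`scene_config`, `simulate_timelapse`, `simulate_exp2_records`,
   `run_pipeline`).

# Calibration model

The optode response follows a two-parameter exponential in the channel
ratio `R = sensor / reference`:

    O2(R) = A * exp(-2 R) + C            [mg l-1]

Two calibration points identify `A` and `C`: air-saturated water
(9.2 mg l-1 at the study temperature) and anoxic water (0 mg l-1). With
mean ratios `R_air` and `R_anox`,

    A = (O2_air - O2_anox) / (exp(-2 R_air) - exp(-2 R_anox))
    C = O2_air - A * exp(-2 R_air)

```{r calibration}
fit <- fit_two_point(R_air = 0.5, R_anoxic = 1.5)
fit
```

`A > 0` and O2 is strictly decreasing in `R`. Calibrated maps are *not*
clamped to `[0, O2_air]`: noise legitimately produces slightly negative or
super-saturated pixel values, and clamping would bias downstream means and
threshold lengths. Pixels with a zero reference signal are masked (`NA`)
rather than silently dropped, and masked pixels poison any interpolated
profile sample that touches them.

# Profiles and threshold lengths

Profiles are sampled along polylines with bilinear interpolation at fixed
arc-length spacing (pixel centres at integer 0-based coordinates).
Two O2 thresholds define the microsite categories, both in mg l-1:

* **hypoxic**: O2 < 1.92 (about 20 % air saturation);
* **suboxic**: O2 < 0.16 (near the detection floor, functionally anoxic).

A *threshold length* is the total arc length where the piecewise-linear
interpolant of the sampled profile is strictly below the threshold.
Crossing positions are found by inverse linear interpolation inside each
bracketing sample pair, and all disjoint sub-threshold segments are
summed. This sub-sample-resolution estimate converges linearly in sample
spacing; the coarser "count samples below threshold times spacing"
estimator is available as `method = "count"` for comparison with
pixel-counting workflows.

Longitudinal profiles are normalized between two anatomical landmarks —
the root cap tip (relative position 0) and the first root hairs (relative
position 1). Samples outside `[0, 1]` are discarded and exact endpoint
samples are inserted by interpolation, so every normalized profile spans
exactly `[0, 1]` and group averaging (`average_profiles`) is well defined
on a common grid. The *mature-zone mean* averages relative positions
0.75–1.0, behind the elongation zone.

```{r thresholds}
p <- o2_profile(seq(0, 50, 10), c(9.2, 9.2, 1.0, 0.1, 1.0, 9.2))
threshold_length(p, 1.92)   # hypoxic length, um
threshold_length(p, 0.16)   # suboxic length, um
```

# Timelapse analysis

Tip tracks are `(time, x, y)` tables. Interval growth rates are Euclidean
cap displacements over elapsed time (um/h); the instantaneous rate at a
timepoint is the mean of its adjacent interval rates (a single interval at
track endpoints). The per-timepoint O2 minimum is the minimum over all
contiguous arc windows of fixed width (default 500 um) of the window-mean
O2 — computed exactly: the cumulative trapezoid integral of the
piecewise-linear profile makes the window mean piecewise quadratic in the
window start, so the global minimum is found from segment breakpoints and
interior stationary points, not from a grid scan. Each timepoint is
assigned a `light`/`dark` period from its hour of day against a
`light_schedule` (default light 06:00–18:00, assignment by membership in
`[light_start, light_end)`).

# Microsite geometry

The suboxic region around a tip is summarized as a solid of revolution:
a cylinder with the transverse suboxic length as diameter and the
longitudinal suboxic length as height,

    V = pi * (L_trans / 2)^2 * L_long    [um^3]

and the time any fixed point near the root surface spends inside the
moving suboxic region is

    t_exp = L_long / v * 60              [min]

with `v` the tip growth rate (um/h). At the study scale —
`L_long = 332` um, `L_trans = 74` um, `v = 621` um/h:

```{r geometry}
suboxic_volume(332, 74)      # ~1.4e6 um^3
exposure_time(332, 621)      # ~32 min
```

Both formulas are deliberate simplifications: the region is not a perfect
cylinder and the rate is not constant, so these are order-of-magnitude
summaries, which is how they should be read.

# Mixed-effects models

Two designs are supported.

* **Gradient experiment**: six response metrics (mature-zone O2, four
  threshold lengths, transverse maximum decrease), `treatment` fixed,
  random intercepts `(1 | device) + (1 | device:root)` — roots nested in
  devices.
* **Timelapse experiment**: windowed O2 minima against growth rate
  (model 1) and additionally treatment, light/dark period and their
  interaction (model 2), random intercept `(1 | treatment:root_id)`.

`fit_lmm` fits by REML through `lme4::lmer` (or `stats::lm` when no random
terms are given). Wald t statistics use residual degrees of freedom
`n - p`. This is simpler and slightly anti-conservative compared with
Satterthwaite approximations; for the balanced designs here the difference
is small, and the choice is documented rather than hidden. Degenerate
fits are flagged (`singular`, `converged`) instead of being silently
accepted. The variance-partition R2 follows the standard
fixed/random/residual decomposition:

    R2_marginal    = var(X beta) / (var(X beta) + sum(sigma2_random) + sigma2_resid)
    R2_conditional = (var(X beta) + sum(sigma2_random)) / (same denominator)

so `0 <= R2_marginal <= R2_conditional <= 1` always holds.

# Synthetic generators

All generators are seeded and parametric so every downstream stage has an
exact oracle.

## Scene generator

The ground-truth field is a separable depletion plume on a straight root
axis (arc position `s`, distance from axis `d`, both um):

    O2(s, d) = O2_bg - [dO2_tip * exp(-(s - s_min)^2 / (2 sigma_L^2))
                        + dO2_mat * logistic((s - rise_pos) / rise_width)]
               * exp(-d^2 / (2 sigma_T^2))

The Gaussian term is the respiring tip; the logistic term raises the
depression to the depressed mature-root plateau. Defaults emulate the
study conditions: background 9.2 mg l-1 (air saturation), a suboxic tip
minimum (~0.08 mg l-1), a mature plateau near 4.4 mg l-1, pixel size
1.6 um, and hypoxic/suboxic longitudinal extents of order 1300/300 um.

Because the field is closed-form, its minimum (`scene_min`) and threshold
crossings (`scene_crossings`) are analytic: the longitudinal crossings by
root-finding on the known expression, the transverse suboxic width in
closed form, `2 sigma_T * sqrt(2 log(D / (O2_bg - threshold)))`. Rendering
inverts the calibration (`R = -log((O2 - C)/A) / 2`), sets a constant
reference channel and `sensor = reference * R`, and applies multiplicative
Gaussian channel noise. `scene_config` rejects any parameterization whose
field minimum does not exceed `C` — the exact condition for the inversion
to be defined — rather than a cruder sufficient bound on
`dO2_tip + dO2_mat`, which would forbid legitimately suboxic tips whenever
the mature rise is far from the tip.

What the generator does **not** emulate: curved root axes, reaction–
diffusion transients, optode photo-bleaching and lateral smearing, or
spatially correlated noise. It is a geometry-and-calibration test bed,
not a physical simulation.

## Timelapse and experiment tables

`simulate_timelapse` produces straight-axis tracks at a constant nominal
rate with Gaussian-dip O2 profiles scaled so the *windowed-minimum*
operator returns an exact target — the window operator is linear in the
profile values, so the scale is `k = (O2_bg - target) / M` with `M` the
windowed minimum depth of the unit dip. True per-timepoint minima follow
the generating linear model (intercept 3.58, growth slope −2.74e−3 per
um/h, treatment effects 0 / −6.42e−3 / 1.92, dark effect 1.46,
interactions −0.884 / −1.99), with per-root intercepts (SD 0.59) and
residual noise (SD 0.74). Those two SDs were derived *before* any model
fitting from the closed-form fixed-effect variance of the balanced design
(growth-rate SD 200 um/h) to place the marginal/conditional R2 of model 2
near 0.49/0.69; they were not tuned against test outcomes.
`simulate_experiment1` reproduces the nested design — 36 roots on
10 devices across 3 treatments over 7 days — with per-metric means at the
study scale.

# End-to-end pipeline

`run_pipeline(run_config(out_dir, seed))` chains
simulate → calibrate → o2map → profile → timelapse → geometry → stats,
writing each intermediate as a plain-text, CSV or 16-bit TIFF artifact and
a `manifest.json` with the seed, a configuration hash and per-artifact md5
checksums. Reruns with the same configuration and seed are byte-identical
on all CSVs (numeric columns are written at 17 significant digits). Any
stage failure aborts with an error naming the stage. A command-line
wrapper is installed at `system.file("scripts/rhizO2-pipeline.R",
package = "rhizO2")`.

# Numerical choices

* Bilinear interpolation uses 0-based pixel-centre coordinates; samples
  within half a pixel of the border are clamped, samples outside error.
* Threshold crossings, window minima and scene minima are computed from
  the piecewise structure (inverse interpolation, piecewise-quadratic
  minimization, `optimize`/`uniroot` at tolerance 1e-10), not by grid
  refinement.
* `lmer` runs with tightened `nloptwrap` tolerances (1e-8) for
  reproducible coefficients across platforms.
* TIFF channels are stored as 16-bit counts (scaled by 65535); text
  images and CSVs keep full double precision.

# Limitations

* The cylinder volume and constant-rate exposure time are intentionally
  coarse summaries of an irregular, moving region.
* Wald t tests with `n - p` residual df are anti-conservative for small
  group counts; treat p-value stars as descriptive.
* The synthetic scene is parametric, not mechanistic: it validates the
  measurement chain, not rhizosphere transport physics.
* Two-point calibration assumes a spatially uniform optode response; no
  per-pixel calibration is implemented.
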