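# Hourly timelapse analysis: interval and instantaneous root growth rates,
# windowed O2 minima along the longitudinal profile, and light/dark labels.

#' Light/dark schedule
#'
#' @param light_start,light_end Hours-of-day bounding the light period,
#'   `0 <= light_start < light_end <= 24`; the default 06:00-18:00 gives the
#'   12 h light / 12 h dark diurnal cycle.
#' @return Object of class `light_schedule`.
#' @export
light_schedule <- function(light_start = 6, light_end = 18) {
  if (!(0 <= light_start && light_start < light_end && light_end <= 24))
    stop("need 0 <= light_start < light_end <= 24")
  structure(list(light_start = light_start, light_end = light_end),
            class = "light_schedule")
}

#' Construct a timelapse track of a growing root tip
#'
#' @param times Hours since the start of imaging, strictly increasing,
#'   >= 2 timepoints.
#' @param cap_positions Two-column matrix of root-cap-edge (x, y)
#'   coordinates in micrometres, one row per timepoint.
#' @param profiles Optional list of longitudinal `o2_profile`s, one per
#'   timepoint (NULL entries allowed for missed acquisitions).
#' @param treatment Treatment label (e.g. `"Sterile"`, `"P_protegens"`,
#'   `"SoilCommunity"`).
#' @param root_id Root identifier.
#' @param schedule A `light_schedule`.
#' @param start_hour Hour-of-day at `times = 0` (default: lights-on).
#' @return Object of class `timelapse_track`.
#' @export
timelapse_track <- function(times, cap_positions, profiles = NULL,
                            treatment = "Sterile", root_id = "root1",
                            schedule = light_schedule(),
                            start_hour = schedule$light_start) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need >= 2 timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing (duplicate timestamps?)")
  cap_positions <- as.matrix(cap_positions)
  if (nrow(cap_positions) != length(times) || ncol(cap_positions) != 2L)
    stop("cap_positions must be a length(times) x 2 matrix")
  if (!is.null(profiles) && length(profiles) != length(times))
    stop("profiles must align with times")
  structure(list(times = times, cap_positions = cap_positions,
                 profiles = profiles, treatment = treatment,
                 root_id = root_id, schedule = schedule,
                 start_hour = start_hour),
            class = "timelapse_track")
}

#' Interval growth rates between consecutive images
#'
#' Euclidean distance between consecutive root-cap positions divided by the
#' elapsed time, giving the growth rate during each unobserved interval.
#'
#' @param track A `timelapse_track`.
#' @return Numeric vector of length `n - 1`, micrometres per hour.
#' @export
interval_growth_rates <- function(track) {
  stopifnot(inherits(track, "timelapse_track"))
  d <- sqrt(rowSums(diff(track$cap_positions)^2))
  d / diff(track$times)
}

#' Instantaneous growth rate at an imaged timepoint
#'
#' Interior timepoints: mean of the interval rates before and after the
#' image. Endpoints: the single adjacent interval rate.
#'
#' @param track A `timelapse_track`.
#' @param i Timepoint index (omit for all timepoints).
#' @return Micrometres per hour (vector if `i` is missing).
#' @export
instantaneous_rate <- function(track, i = NULL) {
  r <- interval_growth_rates(track)
  n <- length(track$times)
  all_rates <- c(r[1L], (r[-length(r)] + r[-1L]) / 2, r[length(r)])
  if (length(r) == 1L) all_rates <- c(r, r)
  if (is.null(i)) return(all_rates)
  if (i < 1L || i > n) stop("index out of range")
  all_rates[i]
}

# exact cumulative integral of the piecewise-linear interpolant
.cum_integral_fun <- function(positions, values) {
  Fk <- c(0, cumsum(diff(positions) * (utils::head(values, -1) + utils::tail(values, -1)) / 2))
  function(x) {
    i <- findInterval(x, positions, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(positions) - 1L)
    fx <- values[i] + (values[i + 1L] - values[i]) *
      (x - positions[i]) / (positions[i + 1L] - positions[i])
    Fk[i] + (x - positions[i]) * (values[i] + fx) / 2
  }
}

#' Windowed O2 minimum of a longitudinal profile
#'
#' The minimum, over all contiguous arc-length windows of width `window`,
#' of the mean O2 within the window ("the lowest 500 um of O2 values along
#' the profile"). Averaging a window rather than taking a single pixel
#' mitigates anomalous pixel values. The minimization is exact for the
#' piecewise-linear interpolant: the windowed mean is piecewise quadratic in
#' the window start, so candidate minima are enumerated at breakpoints and
#' the interior stationary points.
#'
#' `method = "pooled"` instead averages the lowest sampled values totalling
#' `window` of arc length, ignoring contiguity (sensitivity variant).
#'
#' @param p An `o2_profile` with arc length >= `window`.
#' @param window Window width in micrometres (default 500).
#' @param method `"window"` (default, contiguous) or `"pooled"`.
#' @return Mean O2 of the selected span, mg l-1.
#' @export
o2_minimum <- function(p, window = 500, method = c("window", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(p, "o2_profile"))
  ok <- !is.na(p$values)
  pos <- p$positions[ok]; val <- p$values[ok]
  if (length(val) < 2L) stop("need >= 2 valid samples")
  L <- max(pos) - min(pos)
  if (L < window) stop("profile shorter than the averaging window")
  if (method == "pooled") {
    k <- max(1L, round(window / p$spacing))
    return(mean(sort(val)[seq_len(min(k, length(val)))]))
  }
  Fc <- .cum_integral_fun(pos, val)
  f <- function(x) stats::approx(pos, val, xout = x)$y
  a_lo <- min(pos); a_hi <- max(pos) - window
  # breakpoints where the slope of the windowed mean changes
  br <- sort(unique(c(a_lo, a_hi,
                      pos[pos >= a_lo & pos <= a_hi],
                      (pos - window)[(pos - window) >= a_lo & (pos - window) <= a_hi])))
  cand <- br
  # interior stationary points: f(a + window) = f(a), linear on each piece
  for (j in seq_len(length(br) - 1L)) {
    b1 <- br[j]; b2 <- br[j + 1L]
    g1 <- f(b1 + window) - f(b1)
    g2 <- f(b2 + window) - f(b2)
    if (is.finite(g1) && is.finite(g2) && g1 * g2 < 0)
      cand <- c(cand, b1 + g1 / (g1 - g2) * (b2 - b1))
  }
  means <- (Fc(cand + window) - Fc(cand)) / window
  min(means)
}

#' Assign light/dark period labels
#'
#' A time is labelled `"light"` when its hour-of-day falls in
#' `[light_start, light_end)` and `"dark"` otherwise (the dark period is
#' 12 h of continuous darkness under the default schedule).
#'
#' @param times Hours since track start.
#' @param schedule A `light_schedule`.
#' @param start_hour Hour-of-day at `times = 0`.
#' @return Character vector of `"light"`/`"dark"` labels.
#' @export
assign_period <- function(times, schedule = light_schedule(),
                          start_hour = schedule$light_start) {
  tod <- (start_hour + times) %% 24
  ifelse(tod >= schedule$light_start & tod < schedule$light_end, "light", "dark")
}

#' Build per-timepoint growth records from a timelapse track
#'
#' Joins instantaneous growth rate, windowed O2 minimum, light/dark label,
#' treatment and root id into the tidy table consumed by the mixed-effects
#' stage. Timepoints without a profile are dropped with a warning.
#'
#' @param track A `timelapse_track` with `profiles` set.
#' @param window O2-minimum window width, micrometres.
#' @return data.frame with columns `root_id`, `treatment`, `time_h`,
#'   `growth_rate`, `o2_min`, `period`.
#' @export
build_growth_records <- function(track, window = 500) {
  stopifnot(inherits(track, "timelapse_track"))
  if (is.null(track$profiles)) stop("track has no profiles")
  rates <- instantaneous_rate(track)
  period <- assign_period(track$times, track$schedule, track$start_hour)
  has_prof <- !vapply(track$profiles, is.null, logical(1))
  if (any(!has_prof))
    warning(sum(!has_prof), " timepoint(s) without a profile dropped")
  idx <- which(has_prof)
  o2min <- vapply(idx, function(i) o2_minimum(track$profiles[[i]], window),
                  numeric(1))
  data.frame(root_id = track$root_id, treatment = track$treatment,
             time_h = track$times[idx], growth_rate = rates[idx],
             o2_min = o2min, period = period[idx],
             stringsAsFactors = FALSE)
}
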