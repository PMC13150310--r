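# Profile extraction along polylines and root-tip O2 metrics: normalized
# longitudinal profiles, hypoxic/suboxic region lengths, transverse
# decreases, and treatment-level profile averaging.

#' Default anoxic-microsite thresholds
#'
#' Hypoxic: 1.92 mg l-1 O2 (about 20% air saturation), below which aerobic
#' animals are stressed. Suboxic: 0.16 mg l-1 (under 2% air saturation),
#' below which anaerobic denitrification is expected.
#'
#' @param hypoxic,suboxic Thresholds in mg l-1, `0 < suboxic < hypoxic`.
#' @return Named list of class `threshold_config`.
#' @export
threshold_config <- function(hypoxic = 1.92, suboxic = 0.16) {
  if (!(0 < suboxic && suboxic < hypoxic))
    stop("thresholds must satisfy 0 < suboxic < hypoxic")
  structure(list(hypoxic = hypoxic, suboxic = suboxic), class = "threshold_config")
}

#' Construct a sampling polyline
#'
#' @param vertices Two-column matrix of ordered (x, y) pixel coordinates,
#'   0-based, pixel-center convention.
#' @param kind `"longitudinal"` (root cap to root hairs along the axis) or
#'   `"transverse"` (medium to medium across the root).
#' @return An object of class `polyline`.
#' @export
polyline <- function(vertices, kind = c("longitudinal", "transverse")) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("polyline needs >= 2 (x, y) vertices")
  seg <- sqrt(rowSums(diff(vertices)^2))
  if (sum(seg) <= 0) stop("polyline has zero total length")
  structure(list(vertices = vertices, kind = kind,
                 seg_lengths = seg, length_px = sum(seg)),
            class = "polyline")
}

# point on a polyline at arc length s (pixel units), linear along segments
.polyline_point <- function(line, s_px) {
  cum <- c(0, cumsum(line$seg_lengths))
  s_px <- pmin(pmax(s_px, 0), line$length_px)
  idx <- findInterval(s_px, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(line$seg_lengths))
  frac <- (s_px - cum[idx]) / line$seg_lengths[idx]
  v0 <- line$vertices[idx, , drop = FALSE]
  v1 <- line$vertices[idx + 1L, , drop = FALSE]
  v0 + frac * (v1 - v0)
}

# bilinear interpolation at 0-based pixel-center coords; any invalid
# neighbour poisons the sample (NA)
.bilinear <- function(pixels, mask, x, y) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  x0 <- pmin(pmax(floor(x), 0), nc - 2L)
  y0 <- pmin(pmax(floor(y), 0), nr - 2L)
  fx <- x - x0; fy <- y - y0
  i <- function(r, c) (c) * nr + r + 1L  # 0-based row r, col c -> linear index
  p00 <- pixels[i(y0, x0)];     m00 <- mask[i(y0, x0)]
  p01 <- pixels[i(y0, x0 + 1)]; m01 <- mask[i(y0, x0 + 1)]
  p10 <- pixels[i(y0 + 1, x0)]; m10 <- mask[i(y0 + 1, x0)]
  p11 <- pixels[i(y0 + 1, x0 + 1)]; m11 <- mask[i(y0 + 1, x0 + 1)]
  val <- p00 * (1 - fx) * (1 - fy) + p01 * fx * (1 - fy) +
    p10 * (1 - fx) * fy + p11 * fx * fy
  val[!(m00 & m01 & m10 & m11)] <- NA_real_
  val
}

#' Sample an oxygen map along a polyline
#'
#' Values are obtained by bilinear interpolation of the map at points spaced
#' `spacing` micrometres along the polyline's arc length. Samples whose four
#' neighbouring pixels include a masked pixel are invalid (NA).
#'
#' @param map An `o2_map`.
#' @param line A `polyline` lying inside the image.
#' @param spacing Sample spacing, micrometres (default: one pixel).
#' @param landmarks Optional named list/vector with `cap_pos`,
#'   `meristem_pos`, `hair_pos` arc positions in micrometres (longitudinal
#'   profiles).
#' @return An object of class `o2_profile` with `positions` (um, starting at
#'   0, uniform spacing), `values` (mg l-1) and `kind`.
#' @export
sample_profile <- function(map, line, spacing = map$pixel_size, landmarks = NULL) {
  stopifnot(inherits(map, "o2_map"), inherits(line, "polyline"))
  if (spacing <= 0) stop("spacing must be positive")
  nr <- nrow(map$pixels); nc <- ncol(map$pixels)
  v <- line$vertices
  if (any(v[, 1] < 0 | v[, 1] > nc - 1 | v[, 2] < 0 | v[, 2] > nr - 1))
    stop("polyline exits the image bounds")
  total_um <- line$length_px * map$pixel_size
  positions <- seq(0, total_um, by = spacing)
  pts <- .polyline_point(line, positions / map$pixel_size)
  values <- .bilinear(map$pixels, map$mask, pts[, 1], pts[, 2])
  prof <- structure(list(positions = positions, values = values,
                         spacing = spacing, kind = line$kind,
                         cap_pos = NA_real_, meristem_pos = NA_real_,
                         hair_pos = NA_real_),
                    class = "o2_profile")
  if (!is.null(landmarks)) {
    lm <- as.list(landmarks)
    for (f in c("cap_pos", "meristem_pos", "hair_pos"))
      if (!is.null(lm[[f]])) prof[[f]] <- as.numeric(lm[[f]])
    if (is.finite(prof$cap_pos) && is.finite(prof$hair_pos) &&
        prof$cap_pos >= prof$hair_pos)
      stop("cap_pos must precede hair_pos along the profile")
  }
  prof
}

#' Construct a profile directly from positions and values
#'
#' Convenience constructor for profiles not sampled from a map (e.g. read
#' from files or generated synthetically).
#'
#' @param positions Arc positions in micrometres, starting at 0, strictly
#'   increasing with uniform spacing.
#' @param values O2 values, mg l-1.
#' @param kind `"longitudinal"` or `"transverse"`.
#' @param cap_pos,meristem_pos,hair_pos Optional landmark arc positions, um.
#' @return An `o2_profile`.
#' @export
o2_profile <- function(positions, values, kind = "longitudinal",
                       cap_pos = NA_real_, meristem_pos = NA_real_,
                       hair_pos = NA_real_) {
  if (length(positions) != length(values)) stop("positions/values length mismatch")
  if (length(positions) < 2L) stop("a profile needs >= 2 samples")
  d <- diff(positions)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  if (positions[1L] != 0) stop("positions must start at 0")
  if (max(abs(d - d[1L])) > 1e-9 * max(d)) stop("positions must be uniformly spaced")
  structure(list(positions = as.numeric(positions), values = as.numeric(values),
                 spacing = d[1L], kind = kind,
                 cap_pos = cap_pos, meristem_pos = meristem_pos,
                 hair_pos = hair_pos),
            class = "o2_profile")
}

#' Normalize a longitudinal profile to the cap-to-hair axis
#'
#' Re-expresses arc positions as (position - cap) / (hair - cap), so the
#' root-cap edge maps to 0 and the first root hairs to 1. Samples outside
#' [0, 1] are discarded; if the raw profile spans a landmark without a
#' sample exactly on it, an interpolated sample is inserted so the retained
#' endpoints are exactly 0 and 1.
#'
#' @param p An `o2_profile` with `cap_pos` and `hair_pos` set.
#' @return An object of class `normalized_profile` with `rel_positions` in
#'   [0, 1], `values`, and `scale` (cap-to-hair length, um).
#' @export
normalize_longitudinal <- function(p) {
  stopifnot(inherits(p, "o2_profile"))
  if (!is.finite(p$cap_pos) || !is.finite(p$hair_pos))
    stop("landmark error: cap_pos and hair_pos must be set")
  if (p$cap_pos >= p$hair_pos) stop("landmark error: cap_pos must be < hair_pos")
  scale <- p$hair_pos - p$cap_pos
  rel <- (p$positions - p$cap_pos) / scale
  keep <- rel >= 0 & rel <= 1
  rel_k <- rel[keep]; val_k <- p$values[keep]
  interp_at <- function(pos_um) stats::approx(p$positions, p$values, xout = pos_um)$y
  if (length(rel_k) == 0L || min(rel_k) > 0) {
    if (min(p$positions) <= p$cap_pos && max(p$positions) >= p$cap_pos) {
      rel_k <- c(0, rel_k); val_k <- c(interp_at(p$cap_pos), val_k)
    }
  }
  if (length(rel_k) == 0L || max(rel_k) < 1) {
    if (max(p$positions) >= p$hair_pos && min(p$positions) <= p$hair_pos) {
      rel_k <- c(rel_k, 1); val_k <- c(val_k, interp_at(p$hair_pos))
    }
  }
  if (length(rel_k) < 2L) stop("profile does not cover the cap-to-hair region")
  structure(list(rel_positions = rel_k, values = val_k, scale = scale),
            class = "normalized_profile")
}

#' Mean O2 over the mature root-tip window of a normalized profile
#'
#' Averages O2 over normalized positions in the closed interval
#' `[lo, hi]` (default 0.75-1.0, the more mature section between the
#' elongation zone and the first root hairs).
#'
#' @param np A `normalized_profile`.
#' @param lo,hi Window bounds on the normalized axis.
#' @return Mean O2, mg l-1.
#' @export
mean_mature_o2 <- function(np, lo = 0.75, hi = 1.0) {
  stopifnot(inherits(np, "normalized_profile"))
  sel <- np$rel_positions >= lo & np$rel_positions <= hi & !is.na(np$values)
  if (!any(sel)) stop("no samples in the [", lo, ", ", hi, "] window")
  mean(np$values[sel])
}

# shared worker: length (um) of the piecewise-linear interpolant strictly
# below `threshold`, summed over all disjoint sub-threshold segments;
# crossings located by linear interpolation. method "count" instead counts
# sub-threshold samples times spacing (ImageJ-style pixel counting).
.threshold_length_um <- function(positions_um, values, threshold,
                                 method = c("interpolate", "count")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  if (method == "count") {
    spacing <- diff(positions_um)[1L]
    return(sum(values[ok] < threshold) * spacing)
  }
  total <- 0
  n <- length(values)
  for (i in seq_len(n - 1L)) {
    if (!ok[i] || !ok[i + 1L]) next
    a <- values[i]; b <- values[i + 1L]
    ds <- positions_um[i + 1L] - positions_um[i]
    if (a == b) {
      if (a < threshold) total <- total + ds
    } else {
      u <- (threshold - a) / (b - a)
      u <- min(max(u, 0), 1)
      frac <- if (b > a) u else 1 - u
      total <- total + ds * frac
    }
  }
  total
}

#' Arc length of a profile below an O2 threshold
#'
#' Total length, in micrometres, over which the piecewise-linear
#' interpolant of the sampled profile lies strictly below `threshold`. All
#' disjoint sub-threshold segments are summed; crossings between samples are
#' located by linear interpolation, making the measure resolution-
#' independent. `method = "count"` instead counts sub-threshold samples
#' times the spacing, for sensitivity checks against pixel counting.
#'
#' @param p An `o2_profile` or `normalized_profile` (whose `scale` converts
#'   relative positions back to micrometres).
#' @param threshold O2 threshold, mg l-1.
#' @param method `"interpolate"` (default) or `"count"`.
#' @return Length in micrometres (0 when the profile never dips below).
#' @export
threshold_length <- function(p, threshold, method = c("interpolate", "count")) {
  method <- match.arg(method)
  if (inherits(p, "normalized_profile")) {
    pos_um <- p$rel_positions * p$scale
    vals <- p$values
  } else if (inherits(p, "o2_profile")) {
    pos_um <- p$positions
    vals <- p$values
  } else stop("p must be an o2_profile or normalized_profile")
  if (length(vals) < 2L) stop("need >= 2 samples")
  .threshold_length_um(pos_um, vals, threshold, method)
}

#' Transverse root-tip profile metrics
#'
#' Computes the maximum average decrease (mean of the two boundary O2
#' values minus the profile minimum), the minimum's position, hypoxic and
#' suboxic region lengths, and re-centres positions on the minimum (as used
#' when averaging transverse profiles across roots).
#'
#' @param p A transverse `o2_profile` with >= 3 samples.
#' @param thresholds A `threshold_config`.
#' @return List of class `profile_metrics`: `max_decrease`, `min_value`,
#'   `min_position`, `hypoxic_length`, `suboxic_length`, and `centered`
#'   (the profile with positions relative to the minimum).
#' @export
transverse_metrics <- function(p, thresholds = threshold_config()) {
  stopifnot(inherits(p, "o2_profile"))
  ok <- which(!is.na(p$values))
  if (length(ok) < 3L) stop("need >= 3 valid samples")
  first <- p$values[ok[1L]]; last <- p$values[ok[length(ok)]]
  imin <- ok[which.min(p$values[ok])]
  min_value <- p$values[imin]
  min_position <- p$positions[imin]
  max_decrease <- mean(c(first, last)) - min_value
  centered <- p
  centered$positions <- p$positions - min_position
  class(centered) <- c("centered_profile", "o2_profile")
  structure(list(max_decrease = max_decrease,
                 min_value = min_value,
                 min_position = min_position,
                 hypoxic_length = threshold_length(p, thresholds$hypoxic),
                 suboxic_length = threshold_length(p, thresholds$suboxic),
                 centered = centered),
            class = "profile_metrics")
}

#' Longitudinal root-tip profile metrics
#'
#' Normalizes the profile to the cap-to-hair axis and computes the mean
#' mature-zone O2 (normalized positions 0.75-1.0) and hypoxic/suboxic
#' region lengths in micrometres.
#'
#' @param p A longitudinal `o2_profile` with landmarks set.
#' @param thresholds A `threshold_config`.
#' @return List of class `profile_metrics` with `mean_mature_o2`,
#'   `hypoxic_length`, `suboxic_length`, `min_value`, `min_position`, and
#'   the `normalized` profile.
#' @export
longitudinal_metrics <- function(p, thresholds = threshold_config()) {
  np <- normalize_longitudinal(p)
  ok <- which(!is.na(np$values))
  imin <- ok[which.min(np$values[ok])]
  structure(list(mean_mature_o2 = mean_mature_o2(np),
                 hypoxic_length = threshold_length(np, thresholds$hypoxic),
                 suboxic_length = threshold_length(np, thresholds$suboxic),
                 min_value = np$values[imin],
                 min_position = np$rel_positions[imin] * np$scale,
                 normalized = np),
            class = "profile_metrics")
}

#' Average profiles onto a common position grid
#'
#' Each profile is resampled to `grid` by linear interpolation (no
#' extrapolation) and the per-grid-point mean and standard error over the
#' profiles covering that point are returned, as used for treatment-level
#' mean +/- SE profile figures.
#'
#' @param profiles List of `normalized_profile` objects (grid on [0, 1]) or
#'   of minimum-centered transverse `o2_profile`s (grid in um).
#' @param grid Numeric vector of grid positions. Default: 101 points on
#'   [0, 1] for normalized profiles; the intersection of centered supports
#'   at the median spacing for transverse profiles.
#' @return data.frame with `position`, `mean`, `se`, `n`; `se` is NA (and
#'   the point flagged `undercovered`) where fewer than 2 profiles cover it.
#' @export
average_profiles <- function(profiles, grid = NULL) {
  if (length(profiles) < 2L) stop("need >= 2 profiles to average")
  is_norm <- inherits(profiles[[1L]], "normalized_profile")
  get_xy <- function(p) {
    if (inherits(p, "normalized_profile")) list(x = p$rel_positions, y = p$values)
    else list(x = p$positions, y = p$values)
  }
  if (is.null(grid)) {
    if (is_norm) grid <- seq(0, 1, length.out = 101L)
    else {
      los <- vapply(profiles, function(p) min(get_xy(p)$x), numeric(1))
      his <- vapply(profiles, function(p) max(get_xy(p)$x), numeric(1))
      sp <- stats::median(vapply(profiles, function(p) diff(get_xy(p)$x)[1L], numeric(1)))
      grid <- seq(max(los), min(his), by = sp)
    }
  }
  vals <- vapply(profiles, function(p) {
    xy <- get_xy(p)
    ok <- !is.na(xy$y)
    stats::approx(xy$x[ok], xy$y[ok], xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  se <- apply(vals, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  data.frame(position = grid, mean = m, se = se, n = n,
             undercovered = n < 2L)
}
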