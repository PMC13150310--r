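# Ratiometric optode model: luminescence ratio images and the two-point
# exponential calibration O2 = A * exp(-2 R) + C.

#' Construct a single-channel optode image
#'
#' A channel image holds one grayscale luminescence acquisition: either the
#' O2-quenched phosphorescence of the sensor dye or the O2-insensitive
#' fluorescence of the reference dye.
#'
#' @param pixels Numeric matrix of non-negative intensities (arbitrary
#'   units). Rows index y, columns index x.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param channel_role Either `"sensor"` or `"reference"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size, channel_role = c("sensor", "reference")) {
  channel_role <- match.arg(channel_role)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("channel intensities must be finite")
  if (any(pixels < 0)) stop("channel intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um per pixel)")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel_role = channel_role),
            class = "channel_image")
}

#' Construct a luminescence-ratio image
#'
#' @param pixels Numeric matrix of ratios R = sensor / reference.
#' @param pixel_size Micrometres per pixel.
#' @param mask Logical matrix, `TRUE` where the ratio is valid.
#' @return An object of class `ratio_image`.
#' @export
ratio_image <- function(pixels, pixel_size, mask = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(mask)) mask <- is.finite(pixels)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(pixels))) stop("mask dimensions must match pixels")
  if (any(pixels[mask] < 0)) stop("valid luminescence ratios must be >= 0")
  structure(list(pixels = pixels, pixel_size = pixel_size, mask = mask),
            class = "ratio_image")
}

#' Construct a calibrated oxygen map
#'
#' @param pixels Numeric matrix of O2 concentration in mg l-1. Small negative
#'   values arising from channel noise are retained, never clamped, so that
#'   threshold-length metrics stay unbiased.
#' @param pixel_size Micrometres per pixel.
#' @param mask Logical validity matrix.
#' @param provenance Free-text calibration identifier.
#' @return An object of class `o2_map`.
#' @export
o2_map <- function(pixels, pixel_size, mask = NULL, provenance = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(mask)) mask <- is.finite(pixels)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(pixels))) stop("mask dimensions must match pixels")
  if (!all(is.finite(pixels[mask]))) stop("valid O2 values must be finite")
  structure(list(pixels = pixels, pixel_size = pixel_size, mask = mask,
                 provenance = provenance),
            class = "o2_map")
}

#' Pixelwise luminescence ratio of a sensor/reference image pair
#'
#' Computes R = sensor / reference per pixel. Pixels whose reference
#' intensity is zero are masked invalid and excluded from all downstream
#' statistics.
#'
#' @param sensor,reference `channel_image` objects with matching dimensions
#'   and pixel size, with roles `"sensor"` and `"reference"` respectively.
#' @return A `ratio_image`.
#' @export
compute_ratio <- function(sensor, reference) {
  stopifnot(inherits(sensor, "channel_image"), inherits(reference, "channel_image"))
  if (sensor$channel_role != "sensor" || reference$channel_role != "reference")
    stop("channel roles must be sensor and reference, in that order")
  if (!identical(dim(sensor$pixels), dim(reference$pixels)))
    stop("sensor and reference images differ in dimensions")
  if (!isTRUE(all.equal(sensor$pixel_size, reference$pixel_size)))
    stop("sensor and reference images differ in pixel size")
  ref <- reference$pixels
  mask <- ref > 0
  if (!any(mask)) stop("reference channel is zero everywhere; ratio undefined")
  r <- sensor$pixels / ref
  r[!mask] <- NA_real_
  ratio_image(r, sensor$pixel_size, mask)
}

#' Grand mean luminescence ratio over calibration image pairs
#'
#' For each (sensor, reference) pair the per-pixel ratio is averaged over
#' valid pixels; the per-image means are then averaged. This mirrors the
#' calibration practice of acquiring repeated images of a homogeneous
#' channel and averaging the ratio across each whole image.
#'
#' @param pairs List of two-element lists `(sensor, reference)` of
#'   `channel_image` objects, all sharing dimensions.
#' @return Single numeric grand-mean ratio.
#' @export
mean_ratio <- function(pairs) {
  if (length(pairs) < 1L) stop("need at least one image pair")
  per_image <- vapply(pairs, function(p) {
    ri <- compute_ratio(p[[1L]], p[[2L]])
    v <- ri$pixels[ri$mask]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  if (all(is.na(per_image))) stop("no valid pixels in any calibration pair")
  mean(per_image, na.rm = TRUE)
}

#' Two-point exponential calibration fit
#'
#' Solves O2 = A * exp(-2 R) + C through the two calibration endpoints:
#' air-saturated water (default 9.2 mg l-1) and chemically anoxic water
#' (default 0 mg l-1). By construction the fit returns each endpoint O2
#' exactly when applied to its endpoint ratio.
#'
#' @param R_air Mean luminescence ratio in air-saturated water.
#' @param R_anoxic Mean luminescence ratio in anoxic water.
#' @param O2_air,O2_anoxic Endpoint O2 concentrations, mg l-1.
#' @return An object of class `calibration_fit` with elements `A`, `C` and
#'   the endpoints that produced them.
#' @export
fit_two_point <- function(R_air, R_anoxic, O2_air = 9.2, O2_anoxic = 0) {
  stopifnot(is.finite(R_air), is.finite(R_anoxic), is.finite(O2_air), is.finite(O2_anoxic))
  if (R_air == R_anoxic)
    stop("singular calibration: R_air equals R_anoxic")
  A <- (O2_air - O2_anoxic) / (exp(-2 * R_air) - exp(-2 * R_anoxic))
  C <- O2_air - A * exp(-2 * R_air)
  structure(list(A = A, C = C, R_air = R_air, R_anoxic = R_anoxic,
                 O2_air = O2_air, O2_anoxic = O2_anoxic),
            class = "calibration_fit")
}

#' Evaluate a calibration fit at given luminescence ratios
#'
#' @param fit A `calibration_fit`.
#' @param R Numeric vector or matrix of ratios.
#' @return O2 concentration(s), mg l-1.
#' @export
apply_calibration <- function(fit, R) {
  stopifnot(inherits(fit, "calibration_fit"))
  fit$A * exp(-2 * R) + fit$C
}

#' Convert a ratio image to a calibrated oxygen map
#'
#' Applies O2 = A * exp(-2 R) + C pixelwise. The validity mask is
#' propagated; values are not clamped to the physical range, so channel
#' noise can leave small negative concentrations (counted by [o2_qc()]).
#'
#' @param ratio A `ratio_image`.
#' @param fit A `calibration_fit`.
#' @return An `o2_map`.
#' @export
ratio_to_o2 <- function(ratio, fit) {
  stopifnot(inherits(ratio, "ratio_image"), inherits(fit, "calibration_fit"))
  o2 <- apply_calibration(fit, ratio$pixels)
  o2[!ratio$mask] <- NA_real_
  o2_map(o2, ratio$pixel_size, ratio$mask,
         provenance = sprintf("two-point A=%.6g C=%.6g", fit$A, fit$C))
}

#' Quality-control summary of an oxygen map
#'
#' Counts masked pixels and valid pixels falling outside the physically
#' expected range (below the anoxic endpoint or above air saturation).
#'
#' @param map An `o2_map`.
#' @param lo,hi Expected physical range, mg l-1.
#' @return Named list: `n_valid`, `n_masked`, `n_below`, `n_above`.
#' @export
o2_qc <- function(map, lo = 0, hi = 9.2) {
  stopifnot(inherits(map, "o2_map"))
  v <- map$pixels[map$mask]
  list(n_valid = length(v), n_masked = sum(!map$mask),
       n_below = sum(v < lo), n_above = sum(v > hi))
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Two-point optode calibration: O2 = A * exp(-2 R) + C\n")
  cat(sprintf("  A = %.6g mg/l, C = %.6g mg/l\n", x$A, x$C))
  cat(sprintf("  endpoints: R_air = %.6g (%.3g mg/l), R_anoxic = %.6g (%.3g mg/l)\n",
              x$R_air, x$O2_air, x$R_anoxic, x$O2_anoxic))
  invisible(x)
}
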