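# Suboxic microsite geometry: extrapolation of 2D profile metrics to a 3D
# volume, and microbial exposure time at a growing root tip.

#' Suboxic microsite volume from profile lengths
#'
#' Models the suboxic region around the root tip as a solid of revolution:
#' a cylinder whose diameter is the transverse suboxic extent and whose axis
#' length is the longitudinal suboxic extent,
#' V = pi * (transverse / 2)^2 * longitudinal. This assumes the root grows
#' tangentially to the sensing plane and consumes O2 radially and uniformly.
#' With the study-scale inputs (transverse 74 um, longitudinal 332 um) it
#' gives about 1.4e6 um^3.
#'
#' @param longitudinal_length Longitudinal suboxic length, micrometres.
#' @param transverse_length Transverse suboxic length (= diameter), um.
#' @return Volume in cubic micrometres.
#' @export
suboxic_volume <- function(longitudinal_length, transverse_length) {
  if (any(longitudinal_length < 0) || any(transverse_length < 0))
    stop("lengths must be non-negative")
  pi * (transverse_length / 2)^2 * longitudinal_length
}

#' Microbial exposure time to suboxic conditions at a growing tip
#'
#' Time a stationary microorganism spends inside the suboxic region as the
#' root tip grows past: t = suboxic_length / growth_rate, in minutes. At the
#' study-scale inputs (332 um, 621 um/h) this is about 32 min.
#'
#' @param suboxic_length Longitudinal suboxic length, micrometres.
#' @param growth_rate Root growth rate, micrometres per hour; must be > 0
#'   (a stationary root gives unbounded exposure).
#' @return Exposure time in minutes.
#' @export
exposure_time <- function(suboxic_length, growth_rate) {
  if (any(suboxic_length < 0)) stop("suboxic_length must be non-negative")
  if (any(growth_rate <= 0))
    stop("growth_rate must be positive: exposure is undefined for a stationary root")
  suboxic_length / growth_rate * 60
}
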