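# File I/O: 16-bit grayscale TIFF channels, ImageJ "Text Image" matrices,
# calibration fits as key-value text, polylines/landmarks/tracks as CSV.

#' Read a 16-bit grayscale TIFF channel image
#'
#' @param path TIFF file path.
#' @param pixel_size Micrometres per pixel (not stored in plain TIFFs; must
#'   be supplied).
#' @param channel_role `"sensor"` or `"reference"`.
#' @return A `channel_image` with intensities as integer counts.
#' @export
read_channel_tiff <- function(path, pixel_size, channel_role) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop("expected a single-channel grayscale TIFF")
    img <- img[, , 1L]
  }
  channel_image(img, pixel_size, channel_role)
}

#' Write a channel image as a 16-bit grayscale TIFF
#'
#' Intensities are rounded to integer counts and must fit in 0..65535.
#'
#' @param image A `channel_image`.
#' @param path Output path.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "channel_image"))
  counts <- round(image$pixels)
  if (any(counts < 0) || any(counts > 65535))
    stop("intensities out of 16-bit range")
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an ImageJ "Text Image" (whitespace-delimited numeric matrix)
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_text_image <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE,
                              colClasses = "numeric", check.names = FALSE))
}

#' Write a numeric matrix as an ImageJ "Text Image"
#'
#' Row-major whitespace-delimited plain text, no header, full double
#' precision (ImageJ's Save As > Text Image convention).
#'
#' @param mat Numeric matrix.
#' @param path Output path.
#' @export
write_text_image <- function(mat, path) {
  utils::write.table(format(mat, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a calibration fit to a key-value text file
#'
#' Debian-control-style `key: value` records (readable with any text
#' editor), holding A, C, both ratio endpoints, both O2 endpoints and a
#' timestamp.
#'
#' @param fit A `calibration_fit`.
#' @param path Output path.
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  rec <- data.frame(A = format(fit$A, digits = 17),
                    C = format(fit$C, digits = 17),
                    R_air = format(fit$R_air, digits = 17),
                    R_anoxic = format(fit$R_anoxic, digits = 17),
                    O2_air = format(fit$O2_air, digits = 17),
                    O2_anoxic = format(fit$O2_anoxic, digits = 17),
                    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write.dcf(rec, path)
  invisible(path)
}

#' Read a calibration fit written by [write_calibration()]
#'
#' @param path File path.
#' @return A `calibration_fit`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no calibration file at '", path, "'")
  rec <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  fit_two_point(R_air = as.numeric(rec$R_air),
                R_anoxic = as.numeric(rec$R_anoxic),
                O2_air = as.numeric(rec$O2_air),
                O2_anoxic = as.numeric(rec$O2_anoxic))
}

#' Read profile polylines from CSV
#'
#' Expected columns: `image_id`, `profile_id`, `kind`
#' (`longitudinal`/`transverse`), `vertex` (order), `x`, `y`
#' (0-based pixel coordinates, pixel-center convention).
#'
#' @param path CSV path.
#' @return Named list of `polyline` objects keyed by `profile_id`.
#' @export
read_polylines_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "profile_id", "kind", "vertex", "x", "y")
  if (!all(need %in% names(df))) stop("polyline CSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, df$profile_id), function(d) {
    d <- d[order(d$vertex), ]
    pl <- polyline(cbind(d$x, d$y), kind = d$kind[1L])
    pl$image_id <- d$image_id[1L]
    pl
  })
  out
}

#' Read longitudinal landmarks from CSV
#'
#' Expected columns: `profile_id`, `cap_um`, `meristem_um`, `hair_um` —
#' arc-length positions (micrometres from the profile start) of the root-cap
#' edge, the meristem and the first root hairs.
#'
#' @param path CSV path.
#' @return data.frame keyed by `profile_id`.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("profile_id", "cap_um", "hair_um")
  if (!all(need %in% names(df))) stop("landmark CSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read a timelapse cap-position track from CSV
#'
#' Expected columns: `root_id`, `treatment`, `time_h`, `cap_x_um`,
#' `cap_y_um`; optional `profile_file` referencing a per-timepoint profile.
#'
#' @param path CSV path.
#' @return data.frame sorted by root then time.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("root_id", "treatment", "time_h", "cap_x_um", "cap_y_um")
  if (!all(need %in% names(df))) stop("track CSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  df[order(df$root_id, df$time_h), ]
}
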