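#' Optical system configuration
#'
#' Bundles the physical sampling parameters shared by every field and image in
#' a reconstruction: illumination wavelength, detector pixel pitch, refractive
#' index of the propagation medium, and the numerical knobs of the
#' angular-spectrum propagator.
#'
#' @param wavelength Illumination wavelength in micrometres. Default 0.532.
#' @param pixel_pitch Grid sampling pitch in micrometres. Default 1.0.
#' @param medium_index Refractive index of the homogeneous medium between
#'   sample and sensor (>= 1). Default 1.0.
#' @param pad_factor Integer >= 1. Each dimension is padded to
#'   `pad_factor * n` (edge replication) before the FFT to suppress
#'   wrap-around diffraction. `1` disables padding and makes propagation an
#'   exactly unitary/diagonal operation, which the round-trip tests rely on.
#'   Default 2.
#' @param evanescent_policy Either `"zero"` (evanescent and aliasing spatial
#'   frequencies removed; total power non-increasing) or `"keep"` (full
#'   complex-exponential kernel; exactly invertible, intended for round-trip
#'   verification only). Default `"zero"`.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(wavelength = 0.532, pixel_pitch = 1)
#' @export
optical_config <- function(wavelength = 0.532, pixel_pitch = 1.0,
                           medium_index = 1.0, pad_factor = 2L,
                           evanescent_policy = c("zero", "keep")) {
  evanescent_policy <- match.arg(evanescent_policy)
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, is.finite(wavelength),
            wavelength > 0,
            is.numeric(pixel_pitch), length(pixel_pitch) == 1L, is.finite(pixel_pitch),
            pixel_pitch > 0,
            is.numeric(medium_index), length(medium_index) == 1L, medium_index >= 1)
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L)
    stop("pad_factor must be an integer >= 1", call. = FALSE)
  structure(list(wavelength = wavelength, pixel_pitch = pixel_pitch,
                 medium_index = medium_index, pad_factor = pad_factor,
                 evanescent_policy = evanescent_policy),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> lambda = %g um, pitch = %g um, n = %g, pad = %d, evanescent = %s\n",
    x$wavelength, x$pixel_pitch, x$medium_index, x$pad_factor,
    x$evanescent_policy))
  invisible(x)
}

#' Complex optical field on a regular grid
#'
#' A 2-D complex-valued scalar field sampled at the pitch of its
#' [optical_config()], carried together with its axial position `z`
#' (micrometres, increasing from the sample plane towards the sensor).
#'
#' @param values Complex (or real, promoted) matrix; all entries finite.
#' @param config An [optical_config()].
#' @param z Axial position of the sampling plane in micrometres relative to
#'   the sample plane.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, config = optical_config(), z = 0) {
  stopifnot(inherits(config, "optical_config"),
            is.numeric(z) || is.complex(z), length(z) == 1L, is.finite(z))
  if (!is.matrix(values) || nrow(values) == 0L || ncol(values) == 0L)
    stop("values must be a non-empty matrix", call. = FALSE)
  storage.mode(values) <- "complex"
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite", call. = FALSE)
  structure(list(values = values, config = config, z = as.numeric(z)),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d at z = %g um (pitch %g um)\n",
              nrow(x$values), ncol(x$values), x$z, x$config$pixel_pitch))
  invisible(x)
}

#' Nonnegative intensity image
#'
#' A detected (or simulated) hologram intensity: a nonnegative real grid plus
#' the optics metadata and the sample-to-sensor distance it was recorded at.
#'
#' @param values Nonnegative, finite real matrix.
#' @inheritParams complex_field
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, config = optical_config(), z = 0) {
  stopifnot(inherits(config, "optical_config"),
            is.numeric(z), length(z) == 1L, is.finite(z))
  if (!is.matrix(values) || nrow(values) == 0L || ncol(values) == 0L)
    stop("values must be a non-empty matrix", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("intensity values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("intensity values must be nonnegative", call. = FALSE)
  structure(list(values = values, config = config, z = as.numeric(z)),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d at z = %g um, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$z,
              min(x$values), max(x$values)))
  invisible(x)
}

# DFT sample frequencies in cycles/um for an n-point axis at pitch p,
# in native fft() (wrap-around) order.
fft_freq <- function(n, p) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * p)
}
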