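#' Free-space propagation by the angular spectrum method
#'
#' Propagates a sampled complex field by a signed axial distance `dz` using
#' the exact scalar transfer function
#' \deqn{H(f_x, f_y) = \exp\!\left(i\, 2\pi\, dz \left[\sqrt{(n/\lambda)^2 - f_x^2 - f_y^2} - n/\lambda\right]\right)}
#' applied in the spatial-frequency domain (time convention
#' \eqn{e^{-i\omega t}}, so a forward-travelling wave accumulates phase
#' \eqn{+k z}). The co-propagating plane-wave carrier \eqn{e^{ikz}} is
#' divided out, i.e. fields are expressed in the detection-plane reference
#' frame in which the undiffracted reference wave keeps zero phase at every
#' plane: `propagate(1, dz) == 1` exactly. This makes the in-line hologram
#' model `|A + propagate(a, z)|^2` identical to the intensity
#' `|propagate(A + a, z)|^2` of the physically propagated total field. Frequencies with \eqn{f_x^2+f_y^2 > (n/\lambda)^2} are
#' evanescent; under the default `evanescent_policy = "zero"` they are
#' removed, together with frequencies beyond the band limit at which the
#' sampled kernel phase would alias (local phase step exceeding \eqn{\pi}
#' between adjacent frequency samples). Under `"keep"` the full kernel is
#' retained, making propagation exactly invertible, which is useful only for
#' round-trip verification.
#'
#' The grid is edge-replication padded to `pad_factor` times its size before
#' the FFT and cropped afterwards, suppressing periodic wrap-around of
#' diffracted light.
#'
#' @param field A [complex_field()].
#' @param dz Signed propagation distance in micrometres (negative propagates
#'   back towards the sample).
#' @return A [complex_field()] at `z + dz`, same grid shape and config.
#' @examples
#' cfg <- optical_config(pad_factor = 1L)
#' f <- complex_field(matrix(1 + 0i, 32, 32), cfg)
#' g <- propagate(f, 100)        # plane wave: modulus unchanged
#' max(abs(Mod(g$values) - 1))
#' @export
propagate <- function(field, dz) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.numeric(dz) || length(dz) != 1L || !is.finite(dz))
    stop("dz must be a finite scalar", call. = FALSE)
  if (dz == 0) return(field)
  cfg <- field$config
  v <- field$values
  n1 <- nrow(v); n2 <- ncol(v)

  if (cfg$pad_factor > 1L) {
    p1 <- n1 * (cfg$pad_factor - 1L)
    p2 <- n2 * (cfg$pad_factor - 1L)
    v <- pad_edge(v, floor(p1 / 2), ceiling(p1 / 2), floor(p2 / 2), ceiling(p2 / 2))
  }
  w <- propagate_raw(v, dz, cfg)
  if (cfg$pad_factor > 1L) {
    r0 <- floor(n1 * (cfg$pad_factor - 1L) / 2)
    c0 <- floor(n2 * (cfg$pad_factor - 1L) / 2)
    w <- w[r0 + seq_len(n1), c0 + seq_len(n2), drop = FALSE]
  }
  complex_field(w, cfg, field$z + dz)
}

# Unpadded angular-spectrum step on a bare complex matrix.
propagate_raw <- function(v, dz, cfg) {
  m1 <- nrow(v); m2 <- ncol(v)
  fx <- fft_freq(m1, cfg$pixel_pitch)   # rows
  fy <- fft_freq(m2, cfg$pixel_pitch)   # cols
  f2 <- outer(fx^2, fy^2, `+`)
  fmax2 <- (cfg$medium_index / cfg$wavelength)^2
  arg <- fmax2 - f2
  prop <- arg >= 0

  fmax <- sqrt(fmax2)
  kz <- sqrt(abs(arg))              # cycles/um, real part magnitude
  H <- matrix(0i, m1, m2)
  H[prop] <- exp(2i * pi * dz * (kz[prop] - fmax))   # carrier removed
  if (cfg$evanescent_policy == "keep") {
    # decaying (dz > 0) / growing (dz < 0) exponential: exact inverse pair
    H[!prop] <- exp(-2 * pi * dz * kz[!prop]) * exp(-2i * pi * dz * fmax)
  } else {
    # band limit (Matsushima-style): drop frequencies whose sampled kernel
    # phase steps by more than pi between adjacent frequency samples
    df1 <- 1 / (m1 * cfg$pixel_pitch)
    df2 <- 1 / (m2 * cfg$pixel_pitch)
    df <- max(df1, df2)
    # |d phi / d f| = 2 pi |dz| f / sqrt(fmax2 - f2); keep where step <= pi
    with_sqrt <- sqrt(pmax(arg, 0))
    step_ok <- prop & (2 * pi * abs(dz) * sqrt(f2) * df <= pi * pmax(with_sqrt, 1e-300))
    if (any(prop & !step_ok))
      H[!step_ok] <- 0i
  }
  # aliasing diagnostic for the "keep" path (zero policy band-limits instead)
  if (cfg$evanescent_policy == "keep") {
    df <- max(1 / (m1 * cfg$pixel_pitch), 1 / (m2 * cfg$pixel_pitch))
    fedge2 <- max(f2[prop])
    if (fedge2 > 0) {
      denom <- sqrt(max(fmax2 - fedge2, 1e-300))
      if (2 * pi * abs(dz) * sqrt(fedge2) * df > pi * denom)
        warning("propagation kernel aliases at the band edge; ",
                "increase grid size or reduce |dz|", call. = FALSE)
    }
  }
  V <- stats::fft(v)
  w <- stats::fft(V * H, inverse = TRUE) / (m1 * m2)
  w
}

# Edge-replication padding of a matrix.
pad_edge <- function(v, top, bottom, left, right) {
  n1 <- nrow(v); n2 <- ncol(v)
  ri <- c(rep(1L, top), seq_len(n1), rep(n1, bottom))
  ci <- c(rep(1L, left), seq_len(n2), rep(n2, right))
  v[ri, ci, drop = FALSE]
}

#' Simulate an in-line hologram intensity
#'
#' Forms the intensity recorded by a sensor at distance `z` from the sample
#' when a uniform plane reference wave of amplitude `A` co-propagates with
#' the wave `a(x, y)` scattered by the specimen:
#' \deqn{I = |A + a_z|^2 = |A|^2 + |a_z|^2 + A^* a_z + A a_z^*}
#' where \eqn{a_z} is the scattered wave propagated to the sensor plane. The
#' reference is taken to have zero phase at the detection plane, so `A` is a
#' positive real scalar. The self-interference term \eqn{|a_z|^2} is retained
#' in full: the specimens this package models are strongly scattering
#' (scattered-wave RMS of roughly 28--37% of the reference), so dropping it
#' is not a valid approximation.
#'
#' @param object_field [complex_field()] holding the scattered wave
#'   \eqn{a(x, y)} at the sample plane (total transmitted field minus the
#'   reference).
#' @param reference_amplitude Positive real reference amplitude \eqn{|A|}.
#' @param z Sample-to-sensor distance in micrometres (`z = 0` permitted for
#'   tests).
#' @return An [intensity_image()] at `z`.
#' @export
simulate_hologram <- function(object_field, reference_amplitude, z) {
  stopifnot(inherits(object_field, "complex_field"))
  if (!is.numeric(reference_amplitude) || length(reference_amplitude) != 1L ||
      !is.finite(reference_amplitude) || reference_amplitude <= 0)
    stop("reference_amplitude must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z < 0)
    stop("z must be a finite nonnegative scalar", call. = FALSE)
  az <- if (z == 0) object_field else propagate(object_field, z - object_field$z)
  I <- Mod(reference_amplitude + az$values)^2
  intensity_image(I, object_field$config, z)
}

#' Back-propagate a single hologram intensity
#'
#' The square root of the measured intensity is taken as a real field with
#' zero phase (consistent with a zero-phase reference at the detection plane)
#' and propagated back to the sample plane by `-z`. Because the detected
#' phase is lost, the result carries the characteristic twin-image and
#' self-interference artifacts; it is the input that the neural reconstruction
#' network is trained to clean.
#'
#' @param holo An [intensity_image()].
#' @param z Positive sample-to-sensor distance in micrometres.
#' @param reference_amplitude Positive reference amplitude (kept for
#'   interface symmetry; values are not rescaled here).
#' @return A [complex_field()] at the sample plane (`z = 0`).
#' @export
back_propagate <- function(holo, z, reference_amplitude = 1) {
  stopifnot(inherits(holo, "intensity_image"))
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0)
    stop("z must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(reference_amplitude) || reference_amplitude <= 0)
    stop("reference_amplitude must be positive", call. = FALSE)
  if (any(holo$values < 0))
    stop("negative intensity values", call. = FALSE)
  f <- complex_field(sqrt(holo$values) + 0i, holo$config, z)
  propagate(f, -z)
}
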