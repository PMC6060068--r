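#' Transport-of-intensity phase estimate
#'
#' Deterministic single-pass phase estimate from three hologram intensities
#' recorded at increasing sensor heights. Under the paraxial (transport of
#' intensity) approximation with time convention \eqn{e^{-i\omega t}},
#' \deqn{\nabla\cdot(I \nabla \varphi) = -k\, \partial I/\partial z, \qquad
#'       k = 2\pi n / \lambda,}
#' the axial derivative is estimated with the wide finite difference
#' \eqn{(I_{high} - I_{low}) / (z_{high} - z_{low})} and the in-plane
#' intensity is taken at the middle height, where the recovered phase lives.
#' In the classical eight-height protocol the three planes are heights 1, 7
#' and 8, and the phase is recovered at height 7.
#'
#' The elliptic problem is solved spectrally. A first estimate uses Teague's
#' auxiliary potential (\eqn{\nabla\psi \approx I\nabla\varphi}, two
#' regularised inverse Laplacians); because \eqn{I\nabla\varphi} is not
#' exactly curl-free when the intensity is structured, the estimate is then
#' refined by `picard_iterations` fixed-point corrections that drive the
#' residual of the full elliptic equation to zero. Boundary handling follows
#' the optics configuration: with `pad_factor = 1` the world is treated as
#' periodic and the solve is exact on the torus; with `pad_factor > 1` the
#' grids are mirror-extended, which enforces Neumann-like boundaries on
#' physically windowed data at the cost of small fold artifacts.
#'
#' The inverse Laplacian divides by the Laplacian symbol with a Tikhonov
#' offset `regularization_eps * max |symbol|`, which also pins the
#' undetermined piston mode; the returned phase is reduced to zero mean.
#'
#' @param I_low,I_mid,I_high [intensity_image()] objects (or bare matrices)
#'   at strictly increasing heights; identical shapes, strictly positive
#'   after floor clamping at `1e-6 * max`.
#' @param z_low,z_mid,z_high Heights in micrometres (taken from the
#'   `intensity_image` objects when omitted).
#' @param config [optical_config()]; taken from `I_mid` when omitted.
#' @param regularization_eps Relative spectral regularisation, > 0, as a
#'   fraction of the largest (Nyquist) Laplacian eigenvalue magnitude.
#'   Default `1e-6`: large enough to pin the piston mode, small enough not
#'   to attenuate phase structure at field-of-view scales (the Nyquist
#'   eigenvalue exceeds the eigenvalue of FOV-scale modes by a factor of
#'   roughly `(N/2)^2`, so percent-level relative regularisation would crush
#'   all smooth content).
#' @param picard_iterations Number of fixed-point refinements of the full
#'   elliptic equation after the Teague initialisation (default 10; 0
#'   reproduces the plain Teague solution).
#' @return Real matrix of phase values (radians) at the middle height, zero
#'   mean.
#' @export
tie_phase <- function(I_low, I_mid, I_high,
                      z_low = NULL, z_mid = NULL, z_high = NULL,
                      config = NULL, regularization_eps = 1e-6,
                      picard_iterations = 10L) {
  grab <- function(I, z) {
    if (inherits(I, "intensity_image")) list(v = I$values, z = if (is.null(z)) I$z else z)
    else list(v = I, z = z)
  }
  lo <- grab(I_low, z_low); mi <- grab(I_mid, z_mid); hi <- grab(I_high, z_high)
  if (is.null(config))
    config <- if (inherits(I_mid, "intensity_image")) I_mid$config else optical_config()
  if (is.null(lo$z) || is.null(mi$z) || is.null(hi$z))
    stop("heights must be supplied (or carried by the intensity images)", call. = FALSE)
  if (!(lo$z < mi$z && mi$z < hi$z))
    stop("heights must satisfy z_low < z_mid < z_high", call. = FALSE)
  if (!all(dim(lo$v) == dim(mi$v)) || !all(dim(mi$v) == dim(hi$v)))
    stop("intensity grids must be congruent", call. = FALSE)
  if (regularization_eps <= 0)
    stop("regularization_eps must be > 0", call. = FALSE)

  floor_clamp <- function(v) pmax(v, 1e-6 * max(v))
  Ilo <- floor_clamp(lo$v); Imi <- floor_clamp(mi$v); Ihi <- floor_clamp(hi$v)
  if (min(Imi) <= 0) stop("nonpositive intensity after clamping", call. = FALSE)

  k <- 2 * pi * config$medium_index / config$wavelength
  dIdz <- (Ihi - Ilo) / (hi$z - lo$z)

  n1 <- nrow(Imi); n2 <- ncol(Imi)
  periodic <- config$pad_factor == 1L
  if (periodic) {
    m1 <- n1; m2 <- n2
    expand <- function(m) m
    crop <- function(m) m
  } else {
    m1 <- 2L * n1; m2 <- 2L * n2
    expand <- function(m) {
      m2_ <- rbind(m, m[n1:1, , drop = FALSE])
      cbind(m2_, m2_[, n2:1, drop = FALSE])
    }
    crop <- function(m) m[seq_len(n1), seq_len(n2), drop = FALSE]
  }
  p <- config$pixel_pitch
  fx <- fft_freq(m1, p); fy <- fft_freq(m2, p)
  lap_eig <- -4 * pi^2 * outer(fx^2, fy^2, `+`)
  denom <- lap_eig - regularization_eps * max(abs(lap_eig))
  sp <- function(m, mult) {   # spectral op: multiply transform by `mult`
    M <- stats::fft(expand(m))
    crop(Re(stats::fft(M * mult, inverse = TRUE)) / (m1 * m2))
  }
  inv_lap <- function(m) sp(m, 1 / denom)
  d_dx <- function(m) sp(m, matrix(2i * pi * fx, m1, m2))
  d_dy <- function(m) sp(m, matrix(2i * pi * fy, m1, m2, byrow = TRUE))
  div_I_grad <- function(phi) d_dx(Imi * d_dx(phi)) + d_dy(Imi * d_dy(phi))

  rhs <- -k * dIdz
  psi <- inv_lap(rhs)                       # grad(psi) ~ I grad(phi)
  phi <- inv_lap(d_dx(d_dx(psi) / Imi) + d_dy(d_dy(psi) / Imi))
  # fixed-point refinement preconditioned by max(I): the iteration matrix
  # then has spectrum in [0, 1 - min(I)/max(I)], so the correction is
  # contractive for any intensity profile (merely slow when I spans orders
  # of magnitude, where the Teague estimate is returned nearly unchanged)
  Imax <- max(Imi)
  for (it in seq_len(max(0L, as.integer(picard_iterations)))) {
    phi <- phi + inv_lap(rhs - div_I_grad(phi)) / Imax
  }
  phi - mean(phi)
}
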