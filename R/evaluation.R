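#' Structural similarity of the real and imaginary channels
#'
#' Computes the windowed structural similarity index (SSIM) separately on
#' the real parts and on the imaginary parts of two complex-valued images —
#' the protocol used to score holographic reconstructions against the
#' multi-height gold standard. Identical images score exactly 1 in both
#' channels.
#'
#' @param candidate,reference Congruent complex (or real) matrices, or
#'   [complex_field()] objects.
#' @param window Window width (odd, >= 3). Default 11.
#' @param sigma Standard deviation of the Gaussian window; `NULL` selects a
#'   uniform (box) window, useful for checking against the defining formula
#'   on a single full-image window. Default 1.5.
#' @param k1,k2 Stabilisation constants of the SSIM definition (defaults
#'   0.01 and 0.03).
#' @param dynamic_range Value range `L` of the data; by default the observed
#'   `max - min` over both images, per channel.
#' @return Named numeric vector `c(ssim_real =, ssim_imag =)`, each in
#'   (-1, 1].
#' @export
ssim_channels <- function(candidate, reference, window = 11L, sigma = 1.5,
                          k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  cv <- if (inherits(candidate, "complex_field")) candidate$values else candidate
  rv <- if (inherits(reference, "complex_field")) reference$values else reference
  if (!all(dim(cv) == dim(rv)))
    stop("candidate and reference grids must be congruent", call. = FALSE)
  c(ssim_real = ssim_single(Re(cv), Re(rv), window, sigma, k1, k2, dynamic_range),
    ssim_imag = ssim_single(Im(cv), Im(rv), window, sigma, k1, k2, dynamic_range))
}

# plain windowed SSIM on two real matrices
ssim_single <- function(x, y, window = 11L, sigma = 1.5, k1 = 0.01,
                        k2 = 0.03, dynamic_range = NULL) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (k1 <= 0 || k2 <= 0) stop("k1, k2 must be positive", call. = FALSE)
  if (is.null(dynamic_range)) {
    dynamic_range <- max(x, y) - min(x, y)
    if (dynamic_range == 0) dynamic_range <- 1   # identical constants
  }
  w <- if (is.null(sigma)) rep(1, window) else {
    t <- seq(-(window %/% 2), window %/% 2)
    exp(-t^2 / (2 * sigma^2))
  }
  w <- w / sum(w)
  f <- function(m) sep_filter(m, w)
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2
  syy <- f(y * y) - my^2
  sxy <- f(x * y) - mx * my
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
       ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(s)
}

# separable filtering with edge replication
sep_filter <- function(m, w) {
  k <- length(w); h <- k %/% 2
  n1 <- nrow(m); n2 <- ncol(m)
  mp <- pad_edge(m, h, h, h, h)
  # filter along rows
  out1 <- matrix(0, n1, n2 + 2 * h)
  for (i in seq_len(k))
    out1 <- out1 + w[i] * mp[(i - 1) + seq_len(n1), , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (i in seq_len(k))
    out <- out + w[i] * out1[, (i - 1) + seq_len(n2), drop = FALSE]
  out
}

#' Per-cell phase integrals
#'
#' For a phase image and an integer label map, computes for every labelled
#' cell the integral of the background-relative phase over the cell's
#' footprint,
#' \deqn{\sum_{(x,y)\in cell} (\varphi(x,y) - \varphi_{bg})\; p^2
#'       \quad [rad\,\mu m^2],}
#' where \eqn{\varphi_{bg}} is the median phase over the background (label
#' 0) and `p` the pixel pitch. For a homogeneous cell this integral is
#' directly proportional to the cell volume, which makes it a robust
#' morphological readout for red blood cells.
#'
#' @param phase_image Real matrix of phase values (radians).
#' @param labels Integer matrix, same shape; 0 marks background (required,
#'   at least 1% of pixels), positive integers mark cells.
#' @param pixel_pitch Pixel pitch in micrometres.
#' @return An object of class `cell_phase_stats`: list with `per_cell`
#'   (data frame `cell`, `integral`, `area_px`), `background_phase`, and a
#'   `label_digest` used to verify that two stats objects share a label map.
#' @export
phase_integral <- function(phase_image, labels, pixel_pitch = 1) {
  if (!all(dim(phase_image) == dim(labels)))
    stop("phase image and labels must be congruent", call. = FALSE)
  if (!all(is.finite(phase_image)))
    stop("phase image must be finite", call. = FALSE)
  bg <- labels == 0L
  if (sum(bg) < 0.01 * length(labels))
    stop("background (label 0) must cover at least 1% of pixels", call. = FALSE)
  bg_phase <- median(phase_image[bg])
  ids <- sort(unique(labels[labels > 0L]))
  rel <- phase_image - bg_phase
  per <- data.frame(
    cell = ids,
    integral = vapply(ids, function(i) sum(rel[labels == i]) * pixel_pitch^2,
                      numeric(1)),
    area_px = vapply(ids, function(i) sum(labels == i), numeric(1)))
  structure(list(per_cell = per, background_phase = bg_phase,
                 pixel_pitch = pixel_pitch,
                 label_digest = label_digest(labels)),
            class = "cell_phase_stats")
}

label_digest <- function(labels) {
  # order-sensitive checksum of the label map (cheap, no extra deps)
  v <- as.integer(labels)
  c(n = length(v), sum = sum(v), wsum = sum(v * seq_along(v)) %% 2147483647)
}

#' @export
print.cell_phase_stats <- function(x, ...) {
  cat(sprintf("<cell_phase_stats> %d cells, background phase %.4f rad\n",
              nrow(x$per_cell), x$background_phase))
  invisible(x)
}

#' Compare per-cell phase integrals between two reconstructions
#'
#' Pairs the per-cell integrals of two [phase_integral()] results computed
#' on the same label map and reports their Pearson correlation — the
#' cell-volume agreement statistic used to validate single-hologram
#' reconstructions against the multi-height gold standard.
#'
#' @param stats_a,stats_b `cell_phase_stats` objects sharing the label map.
#' @return List with `pairs` (data frame `cell`, `integral_a`,
#'   `integral_b`) and `correlation`.
#' @export
compare_cell_integrals <- function(stats_a, stats_b) {
  stopifnot(inherits(stats_a, "cell_phase_stats"),
            inherits(stats_b, "cell_phase_stats"))
  if (!identical(stats_a$label_digest, stats_b$label_digest))
    stop("phase statistics were not computed on the same label map",
         call. = FALSE)
  if (!identical(stats_a$per_cell$cell, stats_b$per_cell$cell))
    stop("cell id mismatch", call. = FALSE)
  pairs <- data.frame(cell = stats_a$per_cell$cell,
                      integral_a = stats_a$per_cell$integral,
                      integral_b = stats_b$per_cell$integral)
  list(pairs = pairs,
       correlation = stats::cor(pairs$integral_a, pairs$integral_b))
}

#' Defocus tolerance sweep of a trained network
#'
#' Back-propagates a single hologram to a range of defocused planes around
#' the nominal sample-to-sensor distance, feeds each defocused complex field
#' through the fixed trained network, and scores the amplitude of each
#' output against a reference reconstruction with SSIM. With the defaults
#' (±20 um in 1 um steps) the curve has 41 points; a flat top around zero
#' defocus demonstrates tolerance to axial focusing errors.
#'
#' @param net Trained `holo_network`.
#' @param holo [intensity_image()] of the hologram.
#' @param z_center Nominal sample-to-sensor distance (um).
#' @param reference Reference [complex_field()] (or matrix) at the sample
#'   plane.
#' @param z_range Half-width of the sweep in um (default 20).
#' @param dz Step in um (default 1; must be > 0).
#' @return Data frame with columns `defocus_um` and `ssim_amplitude`.
#' @export
defocus_sweep <- function(net, holo, z_center, reference, z_range = 20, dz = 1) {
  stopifnot(inherits(net, "holo_network"), inherits(holo, "intensity_image"))
  if (dz <= 0) stop("dz must be positive", call. = FALSE)
  ref <- if (inherits(reference, "complex_field")) reference$values else reference
  deltas <- seq(-z_range, z_range, by = dz)
  ssims <- vapply(deltas, function(delta) {
    bp <- back_propagate(holo, z_center + delta)
    out <- infer(net, bp)
    ov <- if (inherits(out, "complex_field")) out$values else out
    ssim_single(Mod(ov), Mod(ref))
  }, numeric(1))
  data.frame(defocus_um = deltas, ssim_amplitude = ssims)
}
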