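# Shared fixtures. The synthetic world used throughout the tests is
# periodic (pad_factor = 1): simulation and inversion then share the same
# cyclic boundary model, making exactness properties (round trips, fixed
# points) hold to machine precision.

test_optics <- function(pad_factor = 1L, policy = "zero") {
  optical_config(wavelength = 0.532, pixel_pitch = 1.0, medium_index = 1.0,
                 pad_factor = pad_factor, evanescent_policy = policy)
}

rel_rms <- function(a, b) sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))

# remove the (unobservable) global phase before comparing complex fields
align_phase <- function(u, ref) {
  c <- sum(u * Conj(ref))
  if (Mod(c) == 0) u else u * Conj(c) / Mod(c)
}

random_field <- function(n, seed = 1, config = test_optics()) {
  set.seed(seed)
  complex_field(matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)),
                       n, n), config)
}

# analytic scalar Gaussian beam envelope (carrier removed), waist w0 at z=0
gaussian_beam <- function(n, pitch, w0, wavelength, z) {
  zR <- pi * w0^2 / wavelength
  x <- (seq_len(n) - (n + 1) / 2) * pitch
  r2 <- outer(x^2, x^2, `+`)
  w <- w0 * sqrt(1 + (z / zR)^2)
  gouy <- atan(z / zR)
  amp <- (w0 / w) * exp(-r2 / w^2)
  ph <- if (z == 0) 0 else 2 * pi / wavelength * r2 / (2 * z * (1 + (zR / z)^2))
  amp * exp(1i * (ph - gouy))
}

# memoised scaled-down trained network shared by the acceptance tests
acceptance_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_tile_pairs("blood_smear", n_fov = 4L, fov_size = 256L,
                                grid = 4L, fractions = c(40, 12, 12) / 64,
                                seed = 100, config = test_optics())
      net <- build_network(network_config(feature_maps = 16L,
                                          n_residual_blocks = 2L,
                                          n_scales = 3L, seed = 7))
      net <- train_network(net, ds$tiles, epochs = 30L, learning_rate = 1e-3,
                           patience = 5L, seed = 11)
      cache <<- list(net = net, ds = ds)
    }
    cache
  }
})
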