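# Scalar diffraction engine: angular-spectrum propagation, hologram
# formation, back-propagation.

test_that("propagate: identity and plane-wave eigenfunction", {
  f <- random_field(32)
  expect_identical(propagate(f, 0)$values, f$values)

  plane <- complex_field(matrix(2.5 + 0i, 16, 16), test_optics())
  g <- propagate(plane, 137.3)
  expect_lt(max(abs(Mod(g$values) - 2.5)), 1e-12)
  # carrier-free convention: the reference keeps zero phase at every plane
  expect_lt(max(Mod(g$values - plane$values)), 1e-12)
  expect_equal(g$z, 137.3)
})

test_that("propagate rejects bad arguments", {
  f <- random_field(8)
  expect_error(propagate(f, NA_real_), "finite")
  expect_error(propagate(f, Inf), "finite")
  expect_error(complex_field(matrix(NaN + 0i, 4, 4)), "finite")
})

test_that("propagate matches brute-force Rayleigh-Sommerfeld summation", {
  # 32x32 Gaussian spot, dz = 50 um, lambda = 0.532 um, pitch = 1 um;
  # oracle: direct first-kind RS integral h = z/(2 pi) (1/r - ik) e^{ikr}/r^2
  # evaluated on the padded 64x64 grid by point-by-point summation.
  n <- 32L; p <- 1; lam <- 0.532; dz <- 50
  x <- (seq_len(n) - n / 2 - 0.5) * p
  u0 <- exp(-outer(x^2, x^2, `+`) / 9) + 0i
  cfg <- optical_config(lam, p, pad_factor = 2L)
  ours <- propagate(complex_field(u0, cfg), dz)$values

  np <- 64L
  u0p <- holorec:::pad_edge(u0, 16, 16, 16, 16)
  xp <- (seq_len(np) - np / 2 - 0.5) * p
  k <- 2 * pi / lam
  rs <- matrix(0i, np, np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    r <- sqrt(outer((xp[i] - xp)^2, (xp[j] - xp)^2, `+`) + dz^2)
    h <- dz / (2 * pi) * (1 / r - 1i * k) * exp(1i * k * r) / r^2
    rs[i, j] <- sum(u0p * h) * p^2
  }
  # the RS oracle carries the plane-wave carrier exp(ikz); our kernel is
  # carrier-free, so multiply it back before comparing
  ours_carrier <- ours * exp(2i * pi * dz / lam)
  expect_lt(rel_rms(ours_carrier, rs[17:48, 17:48]), 1e-3)
})

test_that("round trip and semigroup are exact in 'keep' mode without padding", {
  cfg <- test_optics(pad_factor = 1L, policy = "keep")
  f <- random_field(32, seed = 3, config = cfg)
  g <- suppressWarnings(propagate(propagate(f, 137.5), -137.5))
  expect_lt(rel_rms(g$values, f$values), 1e-10)

  ab <- suppressWarnings(propagate(propagate(f, 41.2), 58.8))
  once <- suppressWarnings(propagate(f, 100))
  expect_lt(rel_rms(ab$values, once$values), 1e-10)
})

test_that("power is non-increasing under the zero policy", {
  # coarse sampling relative to the wavelength so that evanescent and
  # band-limited components actually exist on the grid
  cfg <- optical_config(wavelength = 3, pixel_pitch = 1, pad_factor = 1L)
  f <- random_field(32, seed = 4, config = cfg)
  p0 <- sum(Mod(f$values)^2)
  for (dz in c(5, 20, 80)) {
    p1 <- sum(Mod(propagate(f, dz)$values)^2)
    expect_lte(p1, p0 * (1 + 1e-12))
  }
})

test_that("propagated Gaussian beam width matches the analytic w(z)", {
  n <- 256L; p <- 0.5; w0 <- 6; lam <- 0.532; z <- 100
  x <- (seq_len(n) - (n + 1) / 2) * p
  u0 <- exp(-outer(x^2, x^2, `+`) / w0^2) + 0i
  cfg <- optical_config(lam, p, pad_factor = 2L)
  I <- Mod(propagate(complex_field(u0, cfg), z)$values)^2
  wx <- sqrt(4 * sum(I * outer(x^2, rep(1, n))) / sum(I))
  zR <- pi * w0^2 / lam
  expect_lt(abs(wx - w0 * sqrt(1 + (z / zR)^2)) / (w0 * sqrt(1 + (z / zR)^2)),
            0.01)
})

test_that("aliasing kernel warns in keep mode", {
  cfg <- optical_config(0.532, 1, pad_factor = 1L, evanescent_policy = "keep")
  f <- complex_field(matrix(1 + 0i, 16, 16), cfg)
  expect_warning(propagate(f, 5e4), "alias")
})

test_that("simulate_hologram implements the in-line intensity model", {
  cfg <- test_optics()
  # no scatterer: I == |A|^2
  a0 <- complex_field(matrix(0i, 16, 16), cfg)
  I <- simulate_hologram(a0, 1, 100)
  expect_equal(max(abs(I$values - 1)), 0)

  # single pixel a = 0.1i at z = 0: cross terms cancel, I = 1.01 there
  av <- matrix(0i, 16, 16); av[5, 7] <- 0.1i
  I2 <- simulate_hologram(complex_field(av, cfg), 1, 0)
  expect_equal(I2$values[5, 7], 1.01, tolerance = 1e-12)
  expect_equal(I2$values[1, 1], 1, tolerance = 1e-12)

  expect_error(simulate_hologram(a0, 0, 10), "positive")
  expect_error(simulate_hologram(a0, -2, 10), "positive")
})

test_that("hologram energy conservation (Parseval oracle)", {
  cfg <- test_optics()   # fine sampling: no evanescent components on grid
  ph <- generate_phantom("tissue", 128, seed = 2, config = cfg)
  a <- complex_field(ph$scattered, cfg, 0)
  I <- simulate_hologram(a, 1, 300)
  az <- propagate(a, 300)
  lhs <- mean(I$values)
  rhs <- 1 + mean(Mod(az$values)^2) + 2 * Re(mean(az$values))
  expect_lt(abs(lhs - rhs) / rhs, 1e-10)
  # with the cross term averaged out analytically: mean I = |A|^2 + mean|a_z|^2
  # + 2 Re(A* mean a_z); the quadratic part is conserved under propagation
  expect_lt(abs(mean(Mod(az$values)^2) - mean(Mod(a$values)^2)) /
              mean(Mod(a$values)^2), 1e-6)
})

test_that("hologram is invariant under compensated global phase rotation", {
  cfg <- test_optics()
  ph <- generate_phantom("discs", 64, seed = 1, config = cfg)
  a <- ph$scattered
  z <- 200; A <- 1.3; th <- 0.7
  I1 <- Mod(A + propagate(complex_field(a, cfg), z)$values)^2
  # rotate the scattered wave and the reference by the same phasor
  I2 <- Mod(A * exp(1i * th) +
              propagate(complex_field(a * exp(1i * th), cfg), z)$values)^2
  expect_lt(max(abs(I1 - I2)), 1e-12)
})

test_that("back_propagate: reference-only and round-trip cases", {
  cfg <- test_optics()
  a0 <- complex_field(matrix(0i, 32, 32), cfg)
  holo <- simulate_hologram(a0, 1.7, 250)
  bp <- back_propagate(holo, 250)
  expect_lt(max(abs(Mod(bp$values) - 1.7)), 1e-10)
  expect_equal(bp$z, 0)
  expect_error(back_propagate(holo, -5), "positive")
})

test_that("back-propagation of a weak hologram carries the object plus twin", {
  # weakly scattering mixed absorption/phase specimen: the real channel of
  # the raw back-propagation tracks the object (r > 0.5) even though the
  # conjugate (twin) component is present at full strength
  cfg <- test_optics()
  n <- 128L
  set.seed(6)
  f2 <- outer(holorec:::fft_freq(n, 1)^2, holorec:::fft_freq(n, 1)^2, `+`)
  sm <- Re(fft(fft(matrix(rnorm(n * n), n, n)) * exp(-f2 / (2 * 0.04^2)),
               inverse = TRUE)) / n^2
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  t0 <- exp(-0.25 * sm + 0.10i * sm)
  holo <- simulate_hologram(complex_field(t0 - 1, cfg, 0), 1, 300)
  bp <- back_propagate(holo, 300)
  r <- cor(as.vector(Re(bp$values)), as.vector(Re(t0)))
  expect_gt(r, 0.5)

  # twin_energy of the raw back-propagation is 1 by construction
  ph <- generate_phantom("tissue", 128, seed = 6, target_rms_ratio = 0.1,
                         config = cfg)
  holo2 <- simulate_hologram(complex_field(ph$scattered, cfg, 0), 1, ph$base_z)
  bp2 <- back_propagate(holo2, ph$base_z)
  expect_equal(twin_energy(bp2, ph), 1, tolerance = 1e-12)
})
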