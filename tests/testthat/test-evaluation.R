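# SSIM protocol, phase integrals, cell comparisons.

test_that("SSIM of identical images is exactly 1 in both channels", {
  set.seed(1)
  m <- matrix(complex(real = rnorm(64 * 64), imaginary = rnorm(64 * 64)),
              64, 64)
  s <- ssim_channels(m, m)
  expect_equal(unname(s), c(1, 1))
  noisy <- m + matrix(complex(real = rnorm(64 * 64), imaginary = rnorm(64 * 64)),
                      64, 64)
  s2 <- ssim_channels(noisy, m)
  expect_true(all(s2 < 1))
  expect_error(ssim_channels(m, m[1:32, 1:32]), "congruent")
})

test_that("SSIM matches a from-definition brute-force computation", {
  # two fixed 8x8 integer images; oracle recomputes every 5x5 uniform window
  # from the defining formula with the same edge-replication protocol
  set.seed(2)
  x <- matrix(sample(0:15, 64, TRUE), 8, 8)
  y <- matrix(sample(0:15, 64, TRUE), 8, 8)
  win <- 5L; h <- win %/% 2
  L <- max(x, y) - min(x, y)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  xp <- holorec:::pad_edge(x, h, h, h, h)
  yp <- holorec:::pad_edge(y, h, h, h, h)
  vals <- numeric(0)
  for (i in 1:8) for (j in 1:8) {
    wx <- as.vector(xp[i:(i + 2 * h), j:(j + 2 * h)])
    wy <- as.vector(yp[i:(i + 2 * h), j:(j + 2 * h)])
    mx <- mean(wx); my <- mean(wy)
    vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
    cxy <- mean(wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                      ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  ours <- holorec:::ssim_single(x, y, window = win, sigma = NULL)
  expect_equal(ours, mean(vals), tolerance = 1e-12)
})

test_that("SSIM is symmetric in its arguments", {
  set.seed(3)
  a <- matrix(rnorm(40 * 40), 40, 40)
  b <- a + 0.3 * matrix(rnorm(40 * 40), 40, 40)
  expect_equal(holorec:::ssim_single(a, b), holorec:::ssim_single(b, a),
               tolerance = 1e-12)
})

test_that("phase integrals: flat image, exact disc, Gaussian closed form", {
  n <- 100L
  labels <- matrix(0L, n, n)
  labels[30:34, 40:44] <- 1L                   # 25 px cell at pitch 1
  flat <- matrix(0.7, n, n)
  st <- phase_integral(flat, labels, pixel_pitch = 1)
  expect_equal(st$per_cell$integral, 0)

  # uniform relative phase of 1 rad over 25 um^2 -> exactly 25 rad um^2
  img <- matrix(0, n, n); img[labels == 1L] <- 1
  st2 <- phase_integral(img, labels, pixel_pitch = 1)
  expect_identical(st2$per_cell$integral, 25)
  expect_identical(st2$background_phase, 0)

  # Gaussian bump: integral ~ 2 pi sigma^2 phi0 within 2%
  x <- seq_len(n) - n / 2
  phi0 <- 0.8; sig <- 6
  bump <- phi0 * exp(-outer(x^2, x^2, `+`) / (2 * sig^2))
  lab <- matrix(0L, n, n)
  lab[outer(x^2, x^2, `+`) < (5 * sig)^2] <- 1L
  st3 <- phase_integral(bump, lab, pixel_pitch = 1)
  expect_lt(abs(st3$per_cell$integral - 2 * pi * sig^2 * phi0) /
              (2 * pi * sig^2 * phi0), 0.02)
})

test_that("phase integral is invariant to a global phase constant", {
  n <- 64L
  labels <- matrix(0L, n, n); labels[10:20, 10:20] <- 1L
  set.seed(4)
  img <- matrix(rnorm(n * n, sd = 0.1), n, n)
  a <- phase_integral(img, labels)
  b <- phase_integral(img + 1.234, labels)
  expect_equal(a$per_cell$integral, b$per_cell$integral, tolerance = 1e-9)
})

test_that("phase_integral validates the background", {
  labels <- matrix(1L, 32, 32)
  expect_error(phase_integral(matrix(0, 32, 32), labels), "background")
  expect_error(phase_integral(matrix(0, 32, 32), matrix(0L, 16, 16)),
               "congruent")
})

test_that("compare_cell_integrals pairs by cell and detects mismatched labels", {
  n <- 96L
  labels <- matrix(0L, n, n)
  labels[5:14, 5:14] <- 1L; labels[40:49, 40:49] <- 2L; labels[70:79, 20:29] <- 3L
  set.seed(5)
  img <- matrix(rnorm(n * n, sd = 0.2), n, n)
  a <- phase_integral(img, labels)
  expect_equal(compare_cell_integrals(a, a)$correlation, 1)

  # permuted cell ids -> different label map -> rejected
  perm <- labels
  perm[labels == 1L] <- 2L; perm[labels == 2L] <- 1L
  b <- phase_integral(img, perm)
  expect_error(compare_cell_integrals(a, b), "label map")
})

test_that("defocus_sweep argument contract", {
  net <- build_network(network_config(4, 1L, 2L, seed = 1))
  holo <- intensity_image(matrix(1, 32, 32), test_optics(), 300)
  ref <- matrix(1 + 0i, 32, 32)
  expect_error(defocus_sweep(net, holo, 300, ref, dz = 0), "positive")
  curve <- defocus_sweep(net, holo, 300, ref, z_range = 2, dz = 1)
  expect_identical(nrow(curve), 5L)
  expect_equal(curve$defocus_um, seq(-2, 2, by = 1))
  expect_true(all(is.finite(curve$ssim_amplitude)))
  # the zero-defocus entry equals plain back-propagate + infer + SSIM
  bp <- back_propagate(holo, 300)
  direct <- holorec:::ssim_single(Mod(infer(net, bp)$values), Mod(ref))
  expect_equal(curve$ssim_amplitude[curve$defocus_um == 0], direct,
               tolerance = 1e-12)
})
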