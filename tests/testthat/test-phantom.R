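# Synthetic specimen generator and multi-height stack simulation.

test_that("phantom calibration hits the requested scattering ratio", {
  cfg <- test_optics()
  # tissue at the measured tissue-section value
  ph <- generate_phantom("tissue", 128, seed = 1, target_rms_ratio = 0.28,
                         config = cfg)
  expect_gte(measure_rms_ratio(ph), 0.26)
  expect_lte(measure_rms_ratio(ph), 0.30)
  # calibration converges for every sample type at its default ratio
  for (typ in c("blood_smear", "pap_smear", "tissue", "discs")) {
    ph <- generate_phantom(typ, 128, seed = 2, config = cfg)
    tgt <- switch(typ, blood_smear = 0.37, pap_smear = 0.34, 0.28)
    expect_lt(abs(measure_rms_ratio(ph) - tgt), 0.02)
  }
})

test_that("phantom invariants: passivity, scattered = t - 1, weak limit", {
  ph <- generate_phantom("pap_smear", 96, seed = 3, config = test_optics())
  expect_true(all(Mod(ph$transmittance) <= 1 + 1e-9))
  expect_equal(ph$scattered, ph$transmittance - 1)
  weak <- generate_phantom("tissue", 64, seed = 3, target_rms_ratio = 0.02,
                           config = test_optics())
  expect_lt(max(Mod(weak$transmittance - 1)), 0.15)
  expect_lt(abs(measure_rms_ratio(weak) - 0.02), 0.005)
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom("blood_smear", 96, seed = 11)
  b <- generate_phantom("blood_smear", 96, seed = 11)
  c <- generate_phantom("blood_smear", 96, seed = 12)
  expect_identical(a$transmittance, b$transmittance)
  expect_identical(a$labels, b$labels)
  expect_gt(sqrt(mean(Mod(a$transmittance - c$transmittance)^2)), 0)
})

test_that("measure_rms_ratio agrees with a two-pass oracle and handles edge cases", {
  ph <- generate_phantom("tissue", 64, seed = 5)
  # independent arithmetic: explicit two-pass mean of squares
  s <- ph$scattered
  acc <- 0
  for (j in seq_len(ncol(s))) acc <- acc + sum(Mod(s[, j])^2)
  expect_equal(measure_rms_ratio(ph), sqrt(acc / length(s)), tolerance = 1e-12)

  empty <- ph
  empty$scattered <- matrix(0i, 64, 64)
  expect_identical(measure_rms_ratio(empty), 0)

  uni <- ph
  uni$scattered <- matrix(complex(modulus = 0.37,
                                  argument = runif(64 * 64, 0, 2 * pi)), 64, 64)
  expect_equal(measure_rms_ratio(uni), 0.37, tolerance = 1e-12)
})

test_that("generate_stack follows the eight-height protocol", {
  ph <- generate_phantom("tissue", 64, seed = 1, config = test_optics())
  st <- generate_stack(ph)
  expect_length(st$images, 8L)
  expect_equal(st$heights, 300 + c(0, 15, 30, 45, 60, 75, 90, 180))
  expect_true(all(diff(st$heights) > 0))
  expect_equal(vapply(st$images, function(im) im$z, numeric(1)), st$heights)

  expect_error(generate_stack(ph, heights = numeric(0)), "non-empty")
  expect_error(generate_stack(ph, heights = c(10, 5)), "increasing")
  expect_error(generate_stack(ph, heights = c(-5, 10)), "increasing|positive")
})

test_that("no scatterer gives constant reference intensity at all heights", {
  ph <- generate_phantom("tissue", 64, seed = 1, config = test_optics())
  ph$scattered <- matrix(0i, 64, 64)
  ph$transmittance <- matrix(1 + 0i, 64, 64)
  st <- generate_stack(ph, reference_amplitude = 1.5)
  for (im in st$images)
    expect_lt(max(abs(im$values - 2.25)), 1e-12)
})

test_that("shot noise follows Poisson statistics at the photon budget", {
  ph <- generate_phantom("tissue", 128, seed = 7, target_rms_ratio = 0.02,
                         config = test_optics())
  photons <- 10000
  st <- generate_stack(ph, noise_model = "shot", noise_param = photons,
                       seed = 42)
  clean <- generate_stack(ph, noise_model = "none")
  rel_sd <- sd((st$images[[1]]$values - clean$images[[1]]$values) /
                 sqrt(clean$images[[1]]$values))
  expect_lt(abs(rel_sd - 1 / sqrt(photons)) / (1 / sqrt(photons)), 0.10)
  # seeded: identical noise realisation under the same seed
  st2 <- generate_stack(ph, noise_model = "shot", noise_param = photons,
                        seed = 42)
  expect_identical(st$images[[1]]$values, st2$images[[1]]$values)
})

test_that("twin_energy normalisation contract", {
  ph <- generate_phantom("tissue", 64, seed = 9, config = test_optics())
  expect_equal(twin_energy(ph$transmittance, ph), 0, tolerance = 1e-20)
  holo <- simulate_hologram(complex_field(ph$scattered, ph$config, 0), 1,
                            ph$base_z)
  bp <- back_propagate(holo, ph$base_z)
  expect_equal(twin_energy(bp, ph), 1, tolerance = 1e-12)
  expect_error(twin_energy(matrix(0i, 32, 32), ph), "match")
})

test_that("stack heights survive container serialisation unchanged", {
  ph <- generate_phantom("discs", 64, seed = 2, config = test_optics())
  st <- generate_stack(ph, heights = 300 + c(0, 15.25, 30.5, 180.000001))
  path <- tempfile(fileext = ".rds")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_identical(st2$heights, st$heights)
  expect_identical(st2$images[[3]]$values, st$images[[3]]$values)
  expect_identical(st2$config$wavelength, st$config$wavelength)
  unlink(path)
})
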