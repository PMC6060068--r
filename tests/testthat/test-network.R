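# Network construction, differentiation, training loop, inference contracts.

test_that("presets and parameter counts", {
  c16 <- network_config(16)
  c32 <- network_config(32)
  expect_identical(c16$preset, "sample-type-specific")
  expect_identical(c32$preset, "universal")
  n16 <- build_network(c16)$n_parameters
  n32 <- build_network(c32)$n_parameters
  expect_gt(n32, n16)
  # analytic count for a minimal configuration: stem (2*9*F + F), per block
  # 2*(F*9F + F), merge per upsampling block (F*9F + F), head (F*9*2 + 2)
  Fm <- 4L
  net <- build_network(network_config(Fm, n_residual_blocks = 1L, n_scales = 2L))
  expected <- (2 * 9 * Fm + Fm) + 2 * 2 * (Fm * 9 * Fm + Fm) +
    (Fm * 9 * Fm + Fm) + (Fm * 9 * 2 + 2)
  expect_identical(net$n_parameters, expected)
})

test_that("output spatial size equals input for pool-compatible tiles", {
  net <- build_network(network_config(8, n_residual_blocks = 1L, n_scales = 3L))
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  out <- holorec:::net_forward(net, x)$out
  expect_identical(dim(out), dim(x))
  expect_true(all(is.finite(out)))
})

test_that("backpropagation matches numerical gradients", {
  net <- build_network(network_config(3, n_residual_blocks = 1L,
                                      n_scales = 2L, seed = 2))
  set.seed(9)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  tgt <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  fw <- holorec:::net_forward(net, x, keep = TRUE)
  grads <- holorec:::net_backward(net, fw$acts,
                                  2 * (fw$out - tgt) / length(tgt))
  loss_at <- function(params) {
    net$params <- params
    mean((holorec:::net_forward(net, x)$out - tgt)^2)
  }
  set.seed(5)
  for (j in seq_along(net$params)) for (fld in c("w", "b")) {
    pj <- net$params[[j]][[fld]]
    for (idx in sample(length(pj), min(4, length(pj)))) {
      h <- 1e-6
      pp <- net$params; pp[[j]][[fld]][idx] <- pp[[j]][[fld]][idx] + h
      pm <- net$params; pm[[j]][[fld]][idx] <- pm[[j]][[fld]][idx] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      ana <- grads[[j]][[fld]][idx]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-4)
    }
  }
})

toy_tiles <- function(n_train = 6, n_val = 2, size = 16, seed = 4,
                      target_fun = function(m) m) {
  set.seed(seed)
  mk <- function() matrix(complex(real = rnorm(size^2) / 3,
                                  imaginary = rnorm(size^2) / 3), size, size)
  pairs <- lapply(seq_len(n_train + n_val), function(i) {
    m <- mk(); list(input = m, target = target_fun(m), fov = 1L,
                    row = i, col = 1L)
  })
  structure(list(pairs = pairs, grid = 1L, overlap_px = 0L,
                 tile_dim = c(size, size), fov_dim = c(size, size),
                 split = factor(rep(c("train", "validation"),
                                    c(n_train, n_val)),
                                levels = c("train", "validation", "test",
                                           "unassigned"))),
            class = "tile_pair_set")
}

test_that("training reduces the loss on a learnable identity task", {
  tiles <- toy_tiles()
  net <- build_network(network_config(4, n_residual_blocks = 1L,
                                      n_scales = 2L, seed = 3))
  init_loss <- mean(vapply(which(tiles$split == "train"), function(i) {
    p <- tiles$pairs[[i]]
    mean((holorec:::net_forward(net, holorec:::field_to_channels(p$input))$out -
            holorec:::field_to_channels(p$target))^2)
  }, numeric(1)))
  trained <- train_network(net, tiles, epochs = 5, seed = 6)
  expect_lt(trained$training_state$train_loss[5], init_loss)
  expect_length(trained$training_state$validation_loss,
                trained$training_state$epoch)
})

test_that("training is reproducible under a fixed seed", {
  tiles <- toy_tiles()
  net <- build_network(network_config(4, 1L, 2L, seed = 3))
  a <- train_network(net, tiles, epochs = 2, seed = 10)
  b <- train_network(net, tiles, epochs = 2, seed = 10)
  expect_identical(a$params, b$params)
})

test_that("early stopping fires when validation worsens monotonically", {
  # adversarial validation targets: as the network learns the +0.4 shift on
  # the training tiles, the validation loss (targets shifted by -0.4) rises
  tiles <- toy_tiles(n_train = 6, n_val = 2,
                     target_fun = function(m) m + 0.4)
  for (i in which(tiles$split == "validation"))
    tiles$pairs[[i]]$target <- tiles$pairs[[i]]$input - 0.4
  net <- build_network(network_config(4, 1L, 2L, seed = 3))
  patience <- 3L
  trained <- train_network(net, tiles, epochs = 40, patience = patience,
                           seed = 6)
  st <- trained$training_state
  expect_identical(st$stop_reason, "validation_decline")
  expect_lte(st$epoch, st$best_epoch + patience)
  expect_lt(st$epoch, 40L)
})

test_that("training refuses an empty validation split", {
  tiles <- toy_tiles(n_val = 0)
  net <- build_network(network_config(4, 1L, 2L, seed = 3))
  expect_error(train_network(net, tiles), "validation")
})

test_that("infer: tile-sized bypass, cropping, and stitched equivalence", {
  net <- build_network(network_config(4, 1L, 2L, seed = 12))
  set.seed(13)
  m <- matrix(complex(real = rnorm(32 * 32), imaginary = rnorm(32 * 32)),
              32, 32)
  # tile-sized input: stitching bypassed, output equals the raw network pass
  direct <- holorec:::channels_to_field(
    holorec:::net_forward(net, holorec:::field_to_channels(m))$out)
  expect_identical(infer(net, m), direct)

  # odd-sized input is symmetrically cropped to the pooling factor
  modd <- m[1:31, 1:31]
  expect_message(o <- infer(net, modd), "cropping")
  expect_identical(dim(o), c(30L, 30L))

  # larger-than-tile input: output finite, same size, close to the
  # tile-by-tile result in the interior
  net$train_tile <- c(16L, 16L)
  big <- infer(net, m)
  expect_identical(dim(big), dim(m))
  expect_true(all(is.finite(Mod(big))))

  # complex_field wrapper round trip
  cf <- complex_field(m, test_optics(), 0)
  out_cf <- infer(net, cf)
  expect_s3_class(out_cf, "complex_field")
  expect_identical(dim(out_cf$values), dim(m))
})
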