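#' Train the twin-image removal network
#'
#' Minimises the pixelwise mean-squared error between the network output and
#' the target over both channels (real and imaginary parts) with the Adam
#' optimiser, one tile per update step. After every epoch the loss on the
#' validation split is evaluated; the parameters achieving the best
#' validation loss are checkpointed and training stops early once the
#' validation loss has failed to improve for `patience` consecutive epochs —
#' the same guard against over-fitting used when the full-scale networks
#' were trained.
#'
#' @param net A [build_network()] result.
#' @param tiles A [split_dataset()]-assigned `tile_pair_set` with non-empty
#'   train and validation splits. Inputs and targets are complex matrices;
#'   they enter the network as 2-channel (real, imaginary) arrays.
#' @param epochs Maximum number of epochs (default 30).
#' @param learning_rate Adam step size (default 1e-3, the optimiser's
#'   canonical setting, appropriate for the short scaled-down schedules this
#'   package targets).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param seed Seed controlling shuffling (weight initialisation is fixed by
#'   the network's own seed).
#' @param verbose Print per-epoch losses.
#' @return The trained `holo_network` with an added `training_state` element
#'   (class `training_state`): epoch count, `train_loss` and
#'   `validation_loss` histories, `best_epoch` and `stop_reason`
#'   (`"validation_decline"` or `"max_epochs"`). The returned parameters are
#'   the best-validation checkpoint.
#' @export
train_network <- function(net, tiles, epochs = 30L, learning_rate = 1e-3,
                          patience = 5L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "holo_network"), inherits(tiles, "tile_pair_set"))
  tr_idx <- which(tiles$split == "train")
  va_idx <- which(tiles$split == "validation")
  if (length(tr_idx) == 0L) stop("empty training split", call. = FALSE)
  if (length(va_idx) == 0L)
    stop("empty validation split: early stopping undefined", call. = FALSE)

  as_x <- function(p) field_to_channels(p$input)
  as_t <- function(p) field_to_channels(p$target)
  xs <- lapply(tiles$pairs[tr_idx], as_x); ts <- lapply(tiles$pairs[tr_idx], as_t)
  vx <- lapply(tiles$pairs[va_idx], as_x); vt <- lapply(tiles$pairs[va_idx], as_t)

  params <- net$params
  mstate <- lapply(params, function(p) list(w = 0 * p$w, b = 0 * p$b))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0L

  val_loss <- function() {
    net$params <- params
    mean(vapply(seq_along(vx), function(i) {
      out <- net_forward(net, vx[[i]])$out
      mean((out - vt[[i]])^2)
    }, numeric(1)))
  }

  hist_train <- numeric(0); hist_val <- numeric(0)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stop_reason <- "max_epochs"
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(xs))
      tl <- 0
      for (i in ord) {
        net$params <- params
        fw <- net_forward(net, xs[[i]], keep = TRUE)
        err <- fw$out - ts[[i]]
        tl <- tl + mean(err^2)
        grads <- net_backward(net, fw$acts, 2 * err / length(err))
        tstep <- tstep + 1L
        corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
        for (j in seq_along(params)) {
          for (fld in c("w", "b")) {
            g <- grads[[j]][[fld]]
            mstate[[j]][[fld]] <- b1 * mstate[[j]][[fld]] + (1 - b1) * g
            vstate[[j]][[fld]] <- b2 * vstate[[j]][[fld]] + (1 - b2) * g^2
            params[[j]][[fld]] <- params[[j]][[fld]] -
              learning_rate * corr * mstate[[j]][[fld]] /
              (sqrt(vstate[[j]][[fld]]) + eps)
          }
        }
      }
      vl <- val_loss()
      hist_train <- c(hist_train, tl / length(xs))
      hist_val <- c(hist_val, vl)
      if (verbose)
        message(sprintf("epoch %d: train %.5f validation %.5f", ep,
                        tl / length(xs), vl))
      if (vl < best$loss) {
        best <- list(loss = vl, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) {
        stop_reason <- "validation_decline"
        break
      }
    }
  })
  net$params <- best$params
  net$train_tile <- tiles$tile_dim
  net$training_state <- structure(
    list(epoch = length(hist_train), train_loss = hist_train,
         validation_loss = hist_val, best_epoch = best$epoch,
         best_validation_loss = best$loss, stop_reason = stop_reason),
    class = "training_state")
  net
}

#' @export
print.training_state <- function(x, ...) {
  cat(sprintf("<training_state> %d epochs (best %d, val loss %.5g), stopped: %s\n",
              x$epoch, x$best_epoch, x$best_validation_loss, x$stop_reason))
  invisible(x)
}

#' Reconstruct a complex field with a trained network
#'
#' Applies the trained twin-image removal network to a back-propagated
#' single-hologram field. Tile-sized inputs are processed directly; larger
#' fields are divided into overlapping tiles of the training tile size,
#' processed independently, and recombined with linear-feather stitching.
#' Grids not divisible by the network's pooling factor are symmetrically
#' cropped (with a message).
#'
#' @param net A trained `holo_network`.
#' @param field A [complex_field()] (or bare complex matrix): the
#'   back-propagated hologram, normalised so the background is about
#'   `1 + 0i`.
#' @param tile_overlap Overlap in pixels used when the input must be tiled
#'   (default: a quarter of the tile size).
#' @return A [complex_field()] (or matrix, matching the input type) of
#'   identical spatial size.
#' @export
infer <- function(net, field, tile_overlap = NULL) {
  stopifnot(inherits(net, "holo_network"))
  is_cf <- inherits(field, "complex_field")
  v <- if (is_cf) field$values else field
  if (!is.matrix(v)) stop("field must be a matrix or complex_field", call. = FALSE)
  fac <- 2L^(net$config$n_scales - 1L)
  d <- dim(v)
  d2 <- (d %/% fac) * fac
  if (any(d2 != d)) {
    message(sprintf("infer: cropping %dx%d to %dx%d (multiple of %d)",
                    d[1], d[2], d2[1], d2[2], fac))
    o <- (d - d2) %/% 2L
    v <- v[o[1] + seq_len(d2[1]), o[2] + seq_len(d2[2]), drop = FALSE]
    d <- d2
  }

  run_one <- function(m) {
    out <- net_forward(net, field_to_channels(m))$out
    channels_to_field(out)
  }

  tile <- net$train_tile
  if (is.null(tile) || all(d <= tile)) {
    res <- run_one(v)
  } else {
    s <- min(tile[1], d[1], tile[2], d[2])
    s <- (s %/% fac) * fac
    if (is.null(tile_overlap)) tile_overlap <- max(fac, (s %/% 4L) %/% fac * fac)
    # uniform grid of tile start offsets covering d with >= requested overlap
    cover <- function(n) {
      gg <- if (n <= s) 1L else ceiling((n - tile_overlap) / (s - tile_overlap))
      starts <- if (gg == 1L) 0L else round(seq(0, n - s, length.out = gg))
      starts
    }
    st_r <- cover(d[1]); st_c <- cover(d[2])
    num <- matrix(0i, d[1], d[2]); den <- matrix(0, d[1], d[2])
    # linear feather, tapering only on sides that have a neighbouring tile
    win1 <- function(first, last) {
      w <- rep(1, s)
      e <- min(tile_overlap, s %/% 2)
      if (e > 0) {
        t <- seq(0, 1, length.out = e)
        if (!first) w[seq_len(e)] <- t
        if (!last) w[s + 1 - seq_len(e)] <- rev(t)
      }
      w
    }
    for (r0 in st_r) for (c0 in st_c) {
      ri <- r0 + seq_len(s); ci <- c0 + seq_len(s)
      o <- run_one(v[ri, ci, drop = FALSE])
      w <- outer(win1(r0 == st_r[1], r0 == st_r[length(st_r)]),
                 win1(c0 == st_c[1], c0 == st_c[length(st_c)]))
      num[ri, ci] <- num[ri, ci] + o * w
      den[ri, ci] <- den[ri, ci] + w
    }
    den[den == 0] <- 1
    res <- num / den
  }
  if (!all(is.finite(Re(res)) & is.finite(Im(res))))
    stop("non-finite values in network output", call. = FALSE)
  if (is_cf) complex_field(res, field$config, field$z) else res
}
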