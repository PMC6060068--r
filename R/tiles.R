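#' Divide field-of-view image pairs into overlapping tiles
#'
#' Cuts each full field-of-view (FOV) pair — a network input (back-propagated
#' single hologram) and its gold-standard target (multi-height
#' reconstruction, or ground truth for synthetic data) — into a `grid` x
#' `grid` array of square-count sub-tiles overlapping by `overlap_px` pixels
#' in each dimension. With the default 5x5 grid, six FOV pairs yield the
#' canonical dataset of 150 tile pairs. Tiles are ordered row-major within
#' each FOV. If the FOV size `W` is incompatible (tile size
#' `(W + (grid-1)*overlap_px)/grid` not an integer) the FOV is symmetrically
#' cropped to the largest compatible size and a message is emitted.
#'
#' @param full_pairs List of FOV pairs, each `list(input =, target =)` of
#'   congruent complex matrices.
#' @param grid Tiles per dimension (default 5).
#' @param overlap_px Overlap between adjacent tiles in pixels, each
#'   dimension (default 400).
#' @return An object of class `tile_pair_set`: list with `pairs` (each
#'   `list(input, target, fov, row, col)`), `grid`, `overlap_px`,
#'   `tile_dim` (rows, cols), `fov_dim`, and a `split` factor (initially all
#'   `"unassigned"`, see [split_dataset()]).
#' @export
tile_dataset <- function(full_pairs, grid = 5L, overlap_px = 400L) {
  grid <- as.integer(grid); overlap_px <- as.integer(overlap_px)
  stopifnot(length(full_pairs) >= 1L, grid >= 1L, overlap_px >= 0L)
  d <- dim(full_pairs[[1]]$input)

  fit_axis <- function(n) {
    # largest n' <= n with (n' + (g-1)*ov) %% g == 0 and tile > overlap
    np <- n - (n + (grid - 1L) * overlap_px) %% grid
    s <- (np + (grid - 1L) * overlap_px) %/% grid
    if (grid > 1L && s <= overlap_px)
      stop("overlap_px >= tile size; reduce the overlap or the grid",
           call. = FALSE)
    list(n = np, s = s, starts = (seq_len(grid) - 1L) * (s - overlap_px))
  }
  ax_r <- fit_axis(d[1]); ax_c <- fit_axis(d[2])
  if (ax_r$n != d[1] || ax_c$n != d[2])
    message(sprintf("tile_dataset: cropping FOVs from %dx%d to %dx%d for a compatible tiling",
                    d[1], d[2], ax_r$n, ax_c$n))
  off_r <- (d[1] - ax_r$n) %/% 2L; off_c <- (d[2] - ax_c$n) %/% 2L

  pairs <- list()
  for (k in seq_along(full_pairs)) {
    fp <- full_pairs[[k]]
    if (!all(dim(fp$input) == d) || !all(dim(fp$target) == d))
      stop("all FOVs must share the first FOV's dimensions", call. = FALSE)
    for (r in seq_len(grid)) for (cc in seq_len(grid)) {
      ri <- off_r + ax_r$starts[r] + seq_len(ax_r$s)
      ci <- off_c + ax_c$starts[cc] + seq_len(ax_c$s)
      pairs[[length(pairs) + 1L]] <- list(
        input = fp$input[ri, ci, drop = FALSE],
        target = fp$target[ri, ci, drop = FALSE],
        fov = k, row = r, col = cc)
    }
  }
  structure(list(pairs = pairs, grid = grid, overlap_px = overlap_px,
                 tile_dim = c(ax_r$s, ax_c$s), fov_dim = c(ax_r$n, ax_c$n),
                 split = factor(rep("unassigned", length(pairs)),
                                levels = c("train", "validation", "test",
                                           "unassigned"))),
            class = "tile_pair_set")
}

#' @export
print.tile_pair_set <- function(x, ...) {
  tab <- table(x$split)
  cat(sprintf("<tile_pair_set> %d tile pairs (%dx%d px), split: %s\n",
              length(x$pairs), x$tile_dim[1], x$tile_dim[2],
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Assign train/validation/test splits to a tile set
#'
#' Deterministic seeded assignment: validation and test counts are
#' `round(fraction * N)` and every remaining tile goes to training (so 150
#' tiles under the default 2/3, 1/6, 1/6 fractions become 100/25/25). The
#' assignment is FOV-stratified: tiles are interleaved across FOVs in a
#' seeded random order before the validation and test pools are drawn, so
#' every FOV contributes near-proportionally to each split.
#'
#' @param tiles A [tile_dataset()] result.
#' @param fractions Length-3 numeric (train, validation, test) summing to 1.
#' @param seed Integer seed.
#' @return The `tile_pair_set` with its `split` factor assigned.
#' @export
split_dataset <- function(tiles, fractions = c(2 / 3, 1 / 6, 1 / 6), seed = 1L) {
  stopifnot(inherits(tiles, "tile_pair_set"), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  n <- length(tiles$pairs)
  if (n < 3L) stop("need at least 3 tiles to split", call. = FALSE)
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  if (n_val < 1L || n_test < 1L || n - n_val - n_test < 1L)
    stop("fractions leave an empty split", call. = FALSE)

  fovs <- vapply(tiles$pairs, `[[`, integer(1), "fov")
  order_seq <- with_seed(seed, {
    by_fov <- lapply(split(seq_len(n), fovs), sample)
    # interleave FOVs round-robin
    maxlen <- max(lengths(by_fov))
    idx <- unlist(lapply(seq_len(maxlen), function(i)
      unlist(lapply(by_fov, function(v) if (i <= length(v)) v[i] else NULL))),
      use.names = FALSE)
    idx
  })
  split <- rep("train", n)
  split[order_seq[seq_len(n_val)]] <- "validation"
  split[order_seq[n_val + seq_len(n_test)]] <- "test"
  tiles$split <- factor(split, levels = c("train", "validation", "test",
                                          "unassigned"))
  tiles
}

#' Stitch a grid of overlapping tiles back into a full field of view
#'
#' Inverse of [tile_dataset()] for one FOV: overlapping regions are blended
#' with linear feathering (weights ramp linearly from 0 to 1 across the
#' overlap), which reproduces the original FOV exactly when the overlapping
#' tile contents agree.
#'
#' @param tile_list Tiles of one FOV in row-major order (complex or numeric
#'   matrices of identical size).
#' @param grid Tiles per dimension.
#' @param overlap_px Overlap used when tiling.
#' @return A matrix of size `grid*s - (grid-1)*overlap_px` per dimension.
#' @export
stitch_tiles <- function(tile_list, grid, overlap_px) {
  grid <- as.integer(grid); overlap_px <- as.integer(overlap_px)
  stopifnot(length(tile_list) == grid * grid)
  s <- dim(tile_list[[1]])
  ramp <- function(s_) {
    w <- rep(1, s_)
    if (overlap_px > 0) {
      up <- seq(0, 1, length.out = overlap_px)
      list(first = `[<-`(w, s_ - overlap_px + seq_len(overlap_px), rev(up)),
           mid = `[<-`(`[<-`(w, seq_len(overlap_px), up),
                       s_ - overlap_px + seq_len(overlap_px), rev(up)),
           last = `[<-`(w, seq_len(overlap_px), up))
    } else list(first = w, mid = w, last = w)
  }
  wsel <- function(t, g, ramps) {
    if (g == 1L) rep(1, length(ramps$mid))
    else if (t == 1L) ramps$first else if (t == g) ramps$last else ramps$mid
  }
  rr <- ramp(s[1]); rc <- ramp(s[2])
  n1 <- grid * s[1] - (grid - 1L) * overlap_px
  n2 <- grid * s[2] - (grid - 1L) * overlap_px
  num <- matrix(0i, n1, n2); den <- matrix(0, n1, n2)
  step1 <- s[1] - overlap_px; step2 <- s[2] - overlap_px
  k <- 0L
  for (r in seq_len(grid)) for (cc in seq_len(grid)) {
    k <- k + 1L
    w <- outer(wsel(r, grid, rr), wsel(cc, grid, rc))
    ri <- (r - 1L) * step1 + seq_len(s[1])
    ci <- (cc - 1L) * step2 + seq_len(s[2])
    num[ri, ci] <- num[ri, ci] + tile_list[[k]] * w
    den[ri, ci] <- den[ri, ci] + w
  }
  out <- num / den
  if (all(Im(out) == 0)) Re(out) else out
}
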