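#' Simulate a network training set from synthetic phantoms
#'
#' Generates `n_fov` seeded phantoms of one specimen class, simulates a
#' single in-line hologram of each at the phantom's base distance,
#' back-propagates it (the artifact-laden network input), pairs it with the
#' ground-truth transmittance (the gold-standard target for synthetic data,
#' playing the role of the multi-height reconstruction), and tiles and
#' splits the result.
#'
#' @param sample_type Specimen class, see [generate_phantom()].
#' @param n_fov Number of fields of view (default 4).
#' @param fov_size FOV side length in pixels (default 256).
#' @param grid Tiles per dimension per FOV (default 4, i.e. 16 tiles/FOV).
#' @param overlap_px Tile overlap (default 0 for compact synthetic FOVs).
#' @param fractions Train/validation/test fractions for [split_dataset()].
#' @param seed Base seed; phantom `i` uses `seed + i`.
#' @param config [optical_config()]; the default uses `pad_factor = 1`
#'   (periodic synthetic world, self-consistent simulation and inversion).
#' @param target Either `"truth"` (default) or `"multiheight"`; the latter
#'   reconstructs each FOV from a noiseless 8-height stack with the
#'   classical algorithm and uses that as the target, at considerable cost.
#' @param ... Passed to [generate_phantom()] (e.g. `target_rms_ratio`).
#' @return List with `tiles` (a split [tile_dataset()] result), `phantoms`,
#'   and `fovs` (the full-size pairs).
#' @export
simulate_tile_pairs <- function(sample_type = "tissue", n_fov = 4L,
                                fov_size = 256L, grid = 4L, overlap_px = 0L,
                                fractions = c(2 / 3, 1 / 6, 1 / 6),
                                seed = 1L,
                                config = optical_config(pad_factor = 1L),
                                target = c("truth", "multiheight"), ...) {
  target <- match.arg(target)
  phantoms <- lapply(seq_len(n_fov), function(i)
    generate_phantom(sample_type, fov_size, seed = seed + i, config = config,
                     ...))
  fovs <- lapply(phantoms, function(ph) {
    holo <- simulate_hologram(complex_field(ph$scattered, config, 0), 1,
                              ph$base_z)
    bp <- back_propagate(holo, ph$base_z)
    tgt <- if (target == "truth") ph$transmittance else {
      st <- generate_stack(ph)
      recover_subset(st, length(st$heights))$values
    }
    list(input = bp$values, target = tgt)
  })
  tiles <- split_dataset(tile_dataset(fovs, grid = grid,
                                      overlap_px = overlap_px),
                         fractions = fractions, seed = seed)
  list(tiles = tiles, phantoms = phantoms, fovs = fovs)
}
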