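#' Default run configuration
#'
#' A single serialisable list describing a full pipeline run. All defaults
#' equal the canonical acquisition and training protocol: eight sensor
#' heights at +0, 15, 30, 45, 60, 75, 90 and 180 um above the base
#' distance, 50 recovery iterations, 5x5 tiling with 400 px overlap,
#' 2/3-1/6-1/6 split fractions, and the 16/32-feature-map network presets.
#'
#' @param ... Named overrides merged (recursively for sub-lists) over the
#'   defaults.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(seed = 7, simulate = list(sample_type = "blood_smear"))
#' @export
run_config <- function(...) {
  base <- list(
    optics = list(wavelength = 0.532, pixel_pitch = 1.0, medium_index = 1.0,
                  pad_factor = 1L, evanescent_policy = "zero"),
    heights_rel = c(0, 15, 30, 45, 60, 75, 90, 180),
    base_z = 300,
    simulate = list(sample_type = "tissue", grid_size = 256L,
                    target_rms_ratio = NULL, noise_model = "none",
                    noise_param = 10000),
    recovery = list(n_iterations = 50L, n_holo = 8L),
    tiling = list(grid = 5L, overlap_px = 400L,
                  fractions = c(2 / 3, 1 / 6, 1 / 6)),
    network = list(preset = "sample-type-specific", feature_maps = 16L,
                   n_residual_blocks = 4L, n_scales = 3L),
    training = list(epochs = 30L, learning_rate = 1e-3, patience = 5L,
                    n_fov = 4L, fov_size = 256L, tile_grid = 4L),
    paths = list(out = "holorec-out"),
    seed = 1L,
    log_level = "info")
  over <- list(...)
  cfg <- modifyList(base, over)
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration
#'
#' Round-trips a [run_config()] through a human-readable JSON file.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `save_run_config()`: `path` invisibly; `load_run_config()`: the
#'   `run_config`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  cfg <- modifyList(unclass(cfg), obj)
  # jsonlite reads integers back as doubles; normalise the integral knobs
  ints <- function(x) if (is.numeric(x) && all(x == round(x))) as.integer(x) else x
  cfg$optics$pad_factor <- ints(cfg$optics$pad_factor)
  cfg$seed <- ints(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

optics_of <- function(config) {
  do.call(optical_config, config$optics)
}

#' Run one stage of the holographic reconstruction pipeline
#'
#' Executes a named stage with the parameters of a [run_config()], writing
#' its artifacts and a provenance record (config snapshot, seed, package
#' version, timestamp) under `config$paths$out`. Stages:
#'
#' * `simulate` — phantom + multi-height hologram stack
#'   (`stack.rds`, `phantom.rds`, first hologram as `hologram_z1.tif`);
#' * `recover-classical` — multi-height recovery of the simulated stack
#'   (`recon_classical.rds`, `convergence.csv`);
#' * `train` — synthetic tile set + network training
#'   (`model.rds`, `training_curve.csv`);
#' * `infer` — single-hologram network reconstruction
#'   (`recon_network.rds`);
#' * `evaluate` — SSIM of network input/output vs the classical
#'   reconstruction, phase integrals when labels exist
#'   (`evaluation.json`, `cell_integrals.csv`);
#' * `defocus-sweep` — the +-20 um defocus tolerance curve
#'   (`defocus_sweep.csv`).
#'
#' Stages consume the artifacts of earlier stages from the same output
#' directory and fail with an explanatory error when a dependency is
#' missing.
#'
#' @param config A [run_config()].
#' @param command One of `"simulate"`, `"recover-classical"`, `"train"`,
#'   `"infer"`, `"evaluate"`, `"defocus-sweep"`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config = run_config(),
                         command = c("simulate", "recover-classical", "train",
                                     "infer", "evaluate", "defocus-sweep")) {
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command)
  out <- config$paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- optics_of(config)
  pth <- function(f) file.path(out, f)
  need <- function(f, hint) {
    if (!file.exists(pth(f)))
      stop(sprintf("missing artifact '%s' in %s: run `%s` first", f, out,
                   hint), call. = FALSE)
    pth(f)
  }
  artifacts <- list()

  if (command == "simulate") {
    ph <- generate_phantom(config$simulate$sample_type,
                           config$simulate$grid_size, seed = config$seed,
                           target_rms_ratio = config$simulate$target_rms_ratio,
                           config = cfg, base_z = config$base_z)
    st <- generate_stack(ph, heights = config$base_z + config$heights_rel,
                         noise_model = config$simulate$noise_model,
                         noise_param = config$simulate$noise_param,
                         seed = config$seed)
    saveRDS(ph, pth("phantom.rds"))
    write_stack(st, pth("stack.rds"))
    write_hologram(st$images[[1]], pth("hologram_z1.tif"))
    artifacts <- list(phantom = pth("phantom.rds"), stack = pth("stack.rds"),
                      hologram = pth("hologram_z1.tif"))
  } else if (command == "recover-classical") {
    st <- read_stack(need("stack.rds", "simulate"))
    rec <- recover_subset(st, config$recovery$n_holo,
                          multiheight_params(config$recovery$n_iterations))
    write_complex(rec, pth("recon_classical.rds"))
    write.csv(attr(rec, "convergence_log"), pth("convergence.csv"),
              row.names = FALSE)
    artifacts <- list(recon = pth("recon_classical.rds"),
                      convergence = pth("convergence.csv"))
  } else if (command == "train") {
    ds <- simulate_tile_pairs(config$simulate$sample_type,
                              n_fov = config$training$n_fov,
                              fov_size = config$training$fov_size,
                              grid = config$training$tile_grid,
                              seed = config$seed, config = cfg)
    net <- build_network(network_config(config$network$feature_maps,
                                        config$network$n_residual_blocks,
                                        config$network$n_scales,
                                        seed = config$seed))
    net <- train_network(net, ds$tiles, epochs = config$training$epochs,
                         learning_rate = config$training$learning_rate,
                         patience = config$training$patience,
                         seed = config$seed)
    saveRDS(net, pth("model.rds"))
    ts <- net$training_state
    write.csv(data.frame(epoch = seq_along(ts$train_loss),
                         train_loss = ts$train_loss,
                         validation_loss = ts$validation_loss),
              pth("training_curve.csv"), row.names = FALSE)
    artifacts <- list(model = pth("model.rds"),
                      curve = pth("training_curve.csv"))
  } else if (command == "infer") {
    net <- readRDS(need("model.rds", "train"))
    st <- read_stack(need("stack.rds", "simulate"))
    bp <- back_propagate(st$images[[1]], st$heights[1])
    rec <- infer(net, bp)
    write_complex(rec, pth("recon_network.rds"))
    artifacts <- list(recon = pth("recon_network.rds"))
  } else if (command == "evaluate") {
    ref <- read_complex(need("recon_classical.rds", "recover-classical"))
    res <- list()
    st <- read_stack(need("stack.rds", "simulate"))
    bp <- back_propagate(st$images[[1]], st$heights[1])
    res$ssim_input <- as.list(ssim_channels(bp, ref))
    if (file.exists(pth("recon_network.rds"))) {
      recn <- read_complex(pth("recon_network.rds"))
      v <- recn$values
      if (!all(dim(v) == dim(ref$values))) { # network may crop to pool factor
        o <- (dim(ref$values) - dim(v)) %/% 2L
        refv <- ref$values[o[1] + seq_len(nrow(v)), o[2] + seq_len(ncol(v))]
        bpv <- bp$values[o[1] + seq_len(nrow(v)), o[2] + seq_len(ncol(v))]
      } else { refv <- ref$values; bpv <- bp$values }
      res$ssim_output <- as.list(ssim_channels(v, refv))
    }
    if (file.exists(pth("phantom.rds"))) {
      ph <- readRDS(pth("phantom.rds"))
      if (!is.null(ph$labels) && any(ph$labels == 0L)) {
        stats_ref <- phase_integral(Arg(ref$values), ph$labels,
                                    cfg$pixel_pitch)
        write.csv(stats_ref$per_cell, pth("cell_integrals.csv"),
                  row.names = FALSE)
        res$n_cells <- nrow(stats_ref$per_cell)
        artifacts$cells <- pth("cell_integrals.csv")
      }
    }
    jsonlite::write_json(res, pth("evaluation.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    artifacts$evaluation <- pth("evaluation.json")
  } else if (command == "defocus-sweep") {
    net <- readRDS(need("model.rds", "train"))
    st <- read_stack(need("stack.rds", "simulate"))
    ref <- read_complex(need("recon_classical.rds", "recover-classical"))
    curve <- defocus_sweep(net, st$images[[1]], st$heights[1], ref)
    write.csv(curve, pth("defocus_sweep.csv"), row.names = FALSE)
    artifacts <- list(sweep = pth("defocus_sweep.csv"))
  }

  prov <- list(command = command, seed = config$seed,
               package_version = as.character(utils::packageVersion("holorec")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = unclass(config))
  jsonlite::write_json(prov, pth(paste0("provenance_", command, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (identical(config$log_level, "info"))
    message(sprintf("[holorec] %s done -> %s", command, out))
  invisible(artifacts)
}
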