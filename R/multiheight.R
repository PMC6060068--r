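#' Parameters for multi-height phase recovery
#'
#' @param n_iterations Number of full sweeps over the height stack
#'   (default 50, the setting used to generate gold-standard reconstructions;
#'   10--20 already give satisfactory results).
#' @param subset Indices of stack heights to use, sorted ascending; default
#'   all eight.
#' @return An object of class `multiheight_params`.
#' @export
multiheight_params <- function(n_iterations = 50L, subset = 1:8) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("n_iterations must be >= 1", call. = FALSE)
  subset <- as.integer(subset)
  if (length(subset) == 0L || any(is.na(subset)) || is.unsorted(subset, strictly = TRUE))
    stop("subset must be non-empty, sorted, unique", call. = FALSE)
  structure(list(n_iterations = n_iterations, subset = subset),
            class = "multiheight_params")
}

#' Multi-height iterative phase recovery
#'
#' The classical gold-standard reconstruction for in-line holograms of
#' strongly scattering specimens. Starting from an initial phase estimate at
#' the second-highest plane of the subset (the 7th height in the standard
#' eight-height protocol, where the transport-of-intensity estimate lives),
#' the field amplitude is repeatedly replaced by the average of the current
#' amplitude and the measured \eqn{\sqrt{I}} at each plane while the phase is
#' left untouched:
#'
#' 1. guess \eqn{\sqrt{I_{m-1}}\, e^{i\varphi_{init}}} at plane `m-1`
#'    (plane 7 of 8), propagate to the top plane `m`;
#' 2. amplitude \eqn{\leftarrow (|u| + \sqrt{I_m})/2}, phase kept;
#' 3. update sequentially at planes \eqn{m-1, m-2, \ldots, 1} — one
#'    iteration;
#' 4. subsequent iterations propagate from plane 1 back to plane `m` and
#'    repeat; after `n_iterations` sweeps the field is back-propagated from
#'    plane 1 to the sample plane.
#'
#' The data-fidelity residual \eqn{RMS(|u| - \sqrt{I})} is logged before
#' every amplitude update.
#'
#' @param stack A [generate_stack()] result (or equivalent
#'   `hologram_stack`).
#' @param init_phase Real matrix of initial phase (radians) at the
#'   second-highest plane of the subset, e.g. from [tie_phase()]; `NULL`
#'   means a flat zero phase.
#' @param params A [multiheight_params()].
#' @return A [complex_field()] at the sample plane (`z = 0`) with attribute
#'   `convergence_log`: data frame with columns `iteration`, `height_index`,
#'   `residual`.
#' @export
multiheight_recover <- function(stack, init_phase = NULL,
                                params = multiheight_params(
                                  subset = seq_along(stack$heights))) {
  stopifnot(inherits(stack, "hologram_stack"),
            inherits(params, "multiheight_params"))
  sub <- params$subset
  if (any(sub < 1L) || any(sub > length(stack$heights)))
    stop("subset indices outside the stack range", call. = FALSE)
  if (length(sub) < 2L)
    stop("multi-height recovery needs at least 2 heights; ",
         "use back_propagate() for a single hologram", call. = FALSE)
  cfg <- stack$config
  z <- stack$heights[sub]
  sqI <- lapply(stack$images[sub], function(im) sqrt(im$values))
  m <- length(sub)
  shp <- dim(sqI[[1]])
  if (is.null(init_phase)) init_phase <- matrix(0, shp[1], shp[2])
  if (!all(dim(init_phase) == shp))
    stop("init_phase shape does not match stack images", call. = FALSE)

  log_it <- integer(0); log_h <- integer(0); log_r <- numeric(0)
  field <- complex_field(sqI[[m - 1L]] * exp(1i * init_phase), cfg, z[m - 1L])

  # log the data-fidelity residual, then apply the amplitude update
  update_at <- function(field, j, iter) {
    res <- sqrt(mean((Mod(field$values) - sqI[[j]])^2))
    log_it <<- c(log_it, iter); log_h <<- c(log_h, sub[j]); log_r <<- c(log_r, res)
    complex_field(amplitude_update(field$values, sqI[[j]]), cfg, field$z)
  }

  for (iter in seq_len(params$n_iterations)) {
    if (iter == 1L) {
      field <- propagate(field, z[m] - field$z)    # initial 7 -> 8 hop
    } else {
      field <- propagate(field, z[m] - field$z)    # restart: plane 1 -> top
    }
    field <- update_at(field, m, iter)
    for (j in seq.int(m - 1L, 1L)) {
      field <- propagate(field, z[j] - field$z)
      field <- update_at(field, j, iter)
    }
  }
  out <- propagate(field, -field$z)                 # back to sample plane
  attr(out, "convergence_log") <- data.frame(
    iteration = log_it, height_index = log_h, residual = log_r)
  out
}

# Replace the modulus of `values` by the average of the current modulus and
# the measured sqrt-intensity, keeping the phase of every pixel untouched.
amplitude_update <- function(values, sqI) {
  amp <- Mod(values)
  ph <- values / ifelse(amp > 0, amp, 1)      # unit-modulus phase factor
  ph[amp == 0] <- 1 + 0i
  (amp + sqI) / 2 * ph
}

#' Recover with the first N heights only
#'
#' Runs [multiheight_recover()] on the first `n_holo` heights of the stack,
#' reproducing the measurement-count-versus-quality trade-off of the
#' classical method. When the subset still contains the
#' transport-of-intensity triplet (heights 1, 7 and 8 of an eight-height
#' stack) the TIE estimate initialises the phase; otherwise a flat zero
#' phase is used.
#'
#' @param stack A `hologram_stack`.
#' @param n_holo Number of heights to use, between 2 and the stack size.
#' @param params A [multiheight_params()]; its `subset` is replaced by
#'   `1:n_holo`.
#' @return A [complex_field()] at the sample plane, as
#'   [multiheight_recover()].
#' @export
recover_subset <- function(stack, n_holo,
                           params = multiheight_params()) {
  n_holo <- as.integer(n_holo)
  if (is.na(n_holo) || n_holo < 2L)
    stop("n_holo must be an integer >= 2", call. = FALSE)
  if (n_holo > length(stack$heights))
    stop("n_holo exceeds the stack size", call. = FALSE)
  params$subset <- seq_len(n_holo)
  init <- NULL
  if (n_holo >= 8L) {
    init <- tie_phase(stack$images[[1L]], stack$images[[7L]], stack$images[[8L]],
                      config = stack$config)
    params$subset <- seq_len(n_holo)
  }
  multiheight_recover(stack, init_phase = init, params = params)
}
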