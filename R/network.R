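#' Configuration of the twin-image removal network
#'
#' Describes the compact multi-scale residual convolutional network that maps
#' a 2-channel (real, imaginary) back-propagated hologram tile to the
#' artifact-free 2-channel complex image of the same size. Two presets mirror
#' the published design space: `"sample-type-specific"` with 16 feature maps
#' per convolutional layer (one network per specimen class) and
#' `"universal"` with 32 feature maps (a single network for all classes).
#'
#' @param feature_maps Feature maps per convolutional layer. 16 and 32 are
#'   the named presets; any positive integer is accepted.
#' @param n_residual_blocks Residual blocks per scale branch (default 4).
#' @param n_scales Number of parallel resolution branches obtained by
#'   repeated 2x average pooling (default 3); input tiles must be divisible
#'   by `2^(n_scales - 1)`.
#' @param seed Seed for the weight initialisation.
#' @return An object of class `network_config`.
#' @export
network_config <- function(feature_maps = 16L, n_residual_blocks = 4L,
                           n_scales = 3L, seed = 1L) {
  feature_maps <- as.integer(feature_maps)
  n_residual_blocks <- as.integer(n_residual_blocks)
  n_scales <- as.integer(n_scales)
  if (is.na(feature_maps) || feature_maps < 1L)
    stop("feature_maps must be a positive integer", call. = FALSE)
  if (is.na(n_residual_blocks) || n_residual_blocks < 1L)
    stop("n_residual_blocks must be >= 1", call. = FALSE)
  if (is.na(n_scales) || n_scales < 1L)
    stop("n_scales must be >= 1", call. = FALSE)
  preset <- if (feature_maps == 16L) "sample-type-specific"
            else if (feature_maps == 32L) "universal" else "custom"
  structure(list(feature_maps = feature_maps,
                 n_residual_blocks = n_residual_blocks,
                 n_scales = n_scales, channels = 2L,
                 seed = as.integer(seed), preset = preset),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> preset '%s': %d feature maps, %d scales, %d residual blocks/scale\n",
              x$preset, x$feature_maps, x$n_scales, x$n_residual_blocks))
  invisible(x)
}

# -- internal computation-graph builder ------------------------------------
# Nodes are appended in topological order; each node is
# list(op, inputs = integer ids, param = parameter index or NA).
new_graph <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$params <- list()
  env
}
g_node <- function(g, op, inputs = integer(0), param = NA_integer_) {
  g$nodes[[length(g$nodes) + 1L]] <- list(op = op, inputs = as.integer(inputs),
                                          param = param)
  length(g$nodes)
}
g_conv <- function(g, input, c_in, c_out, init_sd = NULL) {
  fan_in <- 9L * c_in
  sd0 <- if (is.null(init_sd)) sqrt(2 / fan_in) else init_sd
  w <- matrix(rnorm(c_out * fan_in, sd = sd0), c_out, fan_in)
  b <- rep(0, c_out)
  g$params[[length(g$params) + 1L]] <- list(w = w, b = b)
  g_node(g, "conv", input, length(g$params))
}

#' Build the multi-scale residual reconstruction network
#'
#' Constructs the fully convolutional computation graph: a stem convolution
#' lifts the 2 input channels to `feature_maps`; the feature tensor is
#' processed in parallel branches at `n_scales` resolutions (2x average
#' pooling between scales), each branch a chain of `n_residual_blocks`
#' pre-activation residual blocks (conv-ReLU-conv plus identity); coarser
#' branches are merged upwards through upsampling blocks
#' (nearest-neighbour upsampling followed by a convolution, added to the next
#' finer branch); a head convolution returns to 2 channels and a global
#' input-to-output residual connection makes the network learn the artifact
#' correction rather than the image itself.
#'
#' @param cfg A [network_config()].
#' @return An object of class `holo_network`; its `n_parameters` element
#'   reports the trainable parameter count.
#' @examples
#' net <- build_network(network_config(feature_maps = 16))
#' net$n_parameters
#' @export
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  F <- cfg$feature_maps
  g <- new_graph()
  with_seed(cfg$seed, {
    input <- g_node(g, "input")
    stem <- g_node(g, "relu", g_conv(g, input, cfg$channels, F))

    # descend: branch inputs at each scale
    branch_in <- integer(cfg$n_scales)
    branch_in[1] <- stem
    if (cfg$n_scales > 1)
      for (s in 2:cfg$n_scales)
        branch_in[s] <- g_node(g, "pool", branch_in[s - 1])

    res_chain <- function(x) {
      for (b in seq_len(cfg$n_residual_blocks)) {
        y <- g_conv(g, x, F, F)
        y <- g_node(g, "relu", y)
        y <- g_conv(g, y, F, F)
        x <- g_node(g, "add", c(x, y))
      }
      x
    }
    branch_out <- vapply(branch_in, res_chain, integer(1))

    # merge coarse-to-fine through upsampling blocks
    merged <- branch_out[cfg$n_scales]
    if (cfg$n_scales > 1)
      for (s in seq.int(cfg$n_scales - 1L, 1L)) {
        up <- g_node(g, "up", merged)
        up <- g_conv(g, up, F, F)
        merged <- g_node(g, "add", c(branch_out[s], up))
      }

    head <- g_conv(g, g_node(g, "relu", merged), F, cfg$channels,
                   init_sd = 1e-2)          # start close to the identity
    out <- g_node(g, "add", c(input, head)) # global residual
    structure(list(nodes = g$nodes, params = g$params, out_node = out,
                   input_node = input, config = cfg,
                   n_parameters = sum(vapply(g$params,
                     function(p) length(p$w) + length(p$b), numeric(1))),
                   train_tile = NULL),
              class = "holo_network")
  })
}

#' @export
print.holo_network <- function(x, ...) {
  cat(sprintf("<holo_network> preset '%s', %d nodes, %s trainable parameters\n",
              x$config$preset, length(x$nodes),
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

# forward pass; x is an H x W x channels array. Returns list(out, acts).
net_forward <- function(net, x, keep = FALSE) {
  acts <- vector("list", length(net$nodes))
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    acts[[i]] <- switch(nd$op,
      input = x,
      conv  = {
        p <- net$params[[nd$param]]
        .conv3_forward(acts[[nd$inputs[1]]], p$w, p$b)
      },
      relu  = pmax(acts[[nd$inputs[1]]], 0),
      pool  = .avgpool2_forward(acts[[nd$inputs[1]]]),
      up    = .upsample2_forward(acts[[nd$inputs[1]]]),
      add   = acts[[nd$inputs[1]]] + acts[[nd$inputs[2]]],
      stop("unknown op ", nd$op))
  }
  out <- acts[[net$out_node]]
  if (keep) list(out = out, acts = acts) else list(out = out, acts = NULL)
}

# backward pass given upstream gradient dout at the output node.
# Returns list(grads = per-param list(w, b)).
net_backward <- function(net, acts, dout) {
  n <- length(net$nodes)
  dacts <- vector("list", n)
  dacts[[net$out_node]] <- dout
  grads <- lapply(net$params, function(p)
    list(w = matrix(0, nrow(p$w), ncol(p$w)), b = rep(0, length(p$b))))
  for (i in seq.int(n, 1L)) {
    d <- dacts[[i]]
    if (is.null(d)) next
    nd <- net$nodes[[i]]
    push <- function(j, g) {
      dacts[[j]] <<- if (is.null(dacts[[j]])) g else dacts[[j]] + g
    }
    switch(nd$op,
      input = NULL,
      conv  = {
        p <- net$params[[nd$param]]
        bk <- .conv3_backward(acts[[nd$inputs[1]]], p$w, d)
        grads[[nd$param]]$w <- grads[[nd$param]]$w + bk$dw
        grads[[nd$param]]$b <- grads[[nd$param]]$b + as.vector(bk$db)
        push(nd$inputs[1], bk$dx)
      },
      relu  = push(nd$inputs[1], d * (acts[[nd$inputs[1]]] > 0)),
      pool  = push(nd$inputs[1], .avgpool2_backward(d)),
      up    = push(nd$inputs[1], .upsample2_backward(d)),
      add   = { push(nd$inputs[1], d); push(nd$inputs[2], d) })
    dacts[[i]] <- NULL   # free
  }
  grads
}

# complex matrix <-> H x W x 2 array (real, imaginary channels)
field_to_channels <- function(v) {
  a <- array(0, c(nrow(v), ncol(v), 2L))
  a[, , 1] <- Re(v); a[, , 2] <- Im(v)
  a
}
channels_to_field <- function(a) {
  matrix(complex(real = a[, , 1], imaginary = a[, , 2]), dim(a)[1], dim(a)[2])
}
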