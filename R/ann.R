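#' Activation functions
#'
#' The three activations used by the networks: the rectified linear unit
#' `max(x, 0)`; the bipolar sigmoid `2 / (1 + exp(-x)) - 1` with range
#' (-1, 1), used for fully-connected hidden nodes; and the logistic sigmoid
#' `1 / (1 + exp(-x))` with range (0, 1), used for output nodes. Arguments
#' to `exp` are clamped to +-500, at which the sigmoids saturate exactly in
#' double precision.
#'
#' @param x numeric vector or matrix.
#' @param kind one of `"relu"`, `"bipolar_sigmoid"`, `"logistic"`.
#' @return same shape as `x`.
#' @export
activation <- function(x, kind) {
  switch(kind,
    relu = pmax(x, 0),
    bipolar_sigmoid = 2 / (1 + exp(-pmin(pmax(x, -500), 500))) - 1,
    logistic = 1 / (1 + exp(-pmin(pmax(x, -500), 500))),
    stop("unknown activation kind: ", kind))
}

# Low-level constructor: a fully-connected network as an ordered list of
# layers, each with weights W (previous size x layer size) and biases b.
new_network <- function(layers, hidden_activation, input_size, output_size,
                        resolution = NA_integer_, spec = NULL) {
  structure(list(layers = layers,
                 hidden_activation = hidden_activation,
                 input_size = as.integer(input_size),
                 output_size = as.integer(output_size),
                 resolution = as.integer(resolution),
                 spec = spec),
            class = "kmc_network")
}

#' Architecture specification for the fully-connected model family
#'
#' The family enumerates five input resolutions, three first-hidden-layer
#' widths and one to three hidden layers. Hidden layers beyond the first
#' share the first layer's width (matching the printed 49-49-49
#' configurations). Output size is always 49, one node per grid box.
#'
#' @param resolution input side length, one of 20, 30, 40, 60, 80.
#' @param hidden_width first hidden layer width, one of 49, 98, 196.
#' @param n_hidden_layers 1, 2 or 3.
#' @return object of class `ann_spec`.
#' @export
ann_spec <- function(resolution, hidden_width, n_hidden_layers) {
  if (!resolution %in% c(20, 30, 40, 60, 80))
    stop("'resolution' must be one of 20, 30, 40, 60, 80")
  if (!hidden_width %in% c(49, 98, 196))
    stop("'hidden_width' must be one of 49, 98, 196")
  if (!n_hidden_layers %in% 1:3)
    stop("'n_hidden_layers' must be 1, 2 or 3")
  structure(list(resolution = as.integer(resolution),
                 hidden_width = as.integer(hidden_width),
                 n_hidden_layers = as.integer(n_hidden_layers)),
            class = "ann_spec")
}

#' @export
format.ann_spec <- function(x, ...) {
  sprintf("ann-%dx%d-%s", x$resolution, x$resolution,
          paste(rep(x$hidden_width, x$n_hidden_layers), collapse = "-"))
}

#' @export
print.ann_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Initialize one layer with the study's ranges: weights uniform in
# [-0.2, 0.2], biases uniform in [0, 0.2]. Consumes the current RNG stream.
init_layer <- function(n_in, n_out,
                       weight_range = c(-0.2, 0.2), bias_range = c(0, 0.2)) {
  list(W = matrix(runif(n_in * n_out, weight_range[1], weight_range[2]),
                  n_in, n_out),
       b = runif(n_out, bias_range[1], bias_range[2]))
}

#' Build and randomly initialize a fully-connected localization network
#'
#' Input size is `resolution^2`, hidden layers all have the spec's width,
#' and the output layer has 49 nodes. Weights start uniform in
#' `[-0.2, +0.2]` and biases uniform in `[0, +0.2]`. Hidden nodes use the
#' bipolar sigmoid and output nodes the logistic sigmoid.
#'
#' @param spec an [ann_spec()].
#' @param seed integer seed for the initialization draw.
#' @return a `kmc_network`.
#' @examples
#' net <- build_ann(ann_spec(30, 49, 3), seed = 1)
#' net$input_size  # 900
#' @export
build_ann <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ann_spec"))
  set.seed(seed)
  widths <- c(spec$resolution^2,
              rep(spec$hidden_width, spec$n_hidden_layers), 49L)
  layers <- lapply(seq_len(length(widths) - 1L), function(k)
    init_layer(widths[k], widths[k + 1L]))
  new_network(layers, "bipolar_sigmoid",
              input_size = spec$resolution^2, output_size = 49L,
              resolution = spec$resolution, spec = spec)
}

#' Forward pass of a fully-connected network
#'
#' Each node j receives `x_j = sum_i w_ij y_i + b_j` over the previous
#' layer; hidden nodes apply the network's hidden activation and output
#' nodes the logistic sigmoid, so outputs lie strictly inside (0, 1).
#'
#' @param net a `kmc_network` without a convolution part.
#' @param input numeric vector of length `net$input_size`, or a matrix with
#'   one row per sample.
#' @return matrix of outputs, one row per sample, `net$output_size` columns.
#' @export
forward_ann <- function(net, input) {
  if (is.vector(input)) input <- matrix(input, nrow = 1L)
  if (ncol(input) != net$input_size)
    stop("input length ", ncol(input), " does not match input_size ",
         net$input_size)
  y <- input
  n_layers <- length(net$layers)
  for (k in seq_len(n_layers)) {
    x <- y %*% net$layers[[k]]$W +
      rep(net$layers[[k]]$b, each = nrow(y))
    kind <- if (k < n_layers) net$hidden_activation else "logistic"
    y <- activation(x, kind)
  }
  y
}

#' Enumerate the 45-model architecture sweep
#'
#' Full cross product of resolutions {20, 30, 40, 60, 80}, first hidden
#' widths {49, 98, 196} and depths {1, 2, 3}, in deterministic order
#' (resolution varying slowest, depth fastest).
#'
#' @return list of 45 [ann_spec()] objects.
#' @export
enumerate_sweep <- function() {
  grid <- expand.grid(n_hidden_layers = 1:3,
                      hidden_width = c(49L, 98L, 196L),
                      resolution = c(20L, 30L, 40L, 60L, 80L))
  grid <- grid[order(grid$resolution, grid$hidden_width,
                     grid$n_hidden_layers), ]
  lapply(seq_len(nrow(grid)), function(i)
    ann_spec(grid$resolution[i], grid$hidden_width[i],
             grid$n_hidden_layers[i]))
}

#' Count scalar parameters of a network
#'
#' @param net a `kmc_network`.
#' @return named integer vector `c(n_weights, n_biases)`; for networks with
#'   a convolution part the 3x3 kernels count as weights and filter biases
#'   as biases.
#' @export
count_parameters <- function(net) {
  nw <- sum(vapply(net$layers, function(l) length(l$W), numeric(1)))
  nb <- sum(vapply(net$layers, function(l) length(l$b), numeric(1)))
  if (!is.null(net$conv)) {
    filters <- unlist(net$conv, recursive = FALSE)
    nw <- nw + 9L * length(filters)
    nb <- nb + length(filters)
  }
  c(n_weights = as.integer(nw), n_biases = as.integer(nb))
}

# --- unified parameter vector -------------------------------------------
# The trainer treats every weight and bias (convolution filters included)
# as one flat variable pool. Order: conv blocks 1..3 (per filter: 9 kernel
# values column-major, then its bias), then fully-connected layers in order
# (W column-major, then b).

net_params <- function(net) {
  conv_part <- if (is.null(net$conv)) numeric(0) else
    unlist(lapply(unlist(net$conv, recursive = FALSE),
                  function(f) c(f$kernel, f$bias)))
  fc_part <- unlist(lapply(net$layers, function(l) c(l$W, l$b)))
  c(conv_part, fc_part)
}

net_bias_mask <- function(net) {
  conv_part <- if (is.null(net$conv)) logical(0) else
    rep(c(rep(FALSE, 9L), TRUE), length(unlist(net$conv, recursive = FALSE)))
  fc_part <- unlist(lapply(net$layers, function(l)
    c(rep(FALSE, length(l$W)), rep(TRUE, length(l$b)))))
  c(conv_part, fc_part)
}

net_set_params <- function(net, params) {
  pos <- 0L
  if (!is.null(net$conv)) {
    for (blk in seq_along(net$conv)) {
      for (f in seq_along(net$conv[[blk]])) {
        net$conv[[blk]][[f]]$kernel <- matrix(params[pos + 1:9], 3L, 3L)
        net$conv[[blk]][[f]]$bias <- params[pos + 10L]
        pos <- pos + 10L
      }
    }
  }
  for (k in seq_along(net$layers)) {
    nw <- length(net$layers[[k]]$W)
    nb <- length(net$layers[[k]]$b)
    net$layers[[k]]$W <- matrix(params[pos + seq_len(nw)],
                                nrow(net$layers[[k]]$W),
                                ncol(net$layers[[k]]$W))
    net$layers[[k]]$b <- params[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  stopifnot(pos == length(params))
  net
}

#' Forward pass dispatching on the network structure
#'
#' @param net a `kmc_network`, with or without a convolution part.
#' @param input matrix of row-major flattened normalized inputs (one row per
#'   sample) or a single vector.
#' @return output matrix, one row per sample.
#' @export
forward_net <- function(net, input) {
  if (is.null(net$conv)) forward_ann(net, input) else forward_cnn(net, input)
}

#' @export
print.kmc_network <- function(x, ...) {
  np <- count_parameters(x)
  widths <- c(x$input_size,
              vapply(x$layers, function(l) length(l$b), numeric(1)))
  if (is.null(x$conv)) {
    cat("Fully-connected localization network\n")
  } else {
    cat("Tree-structured convolution localization network\n")
    cat(sprintf("  conv part: %d + %d + %d per-map 3x3 filters\n",
                length(x$conv[[1]]), length(x$conv[[2]]),
                length(x$conv[[3]])))
  }
  cat(sprintf("  nodes: %s; hidden activation: %s\n",
              paste(widths, collapse = " -> "), x$hidden_activation))
  cat(sprintf("  parameters: %d weights + %d biases\n",
              np["n_weights"], np["n_biases"]))
  invisible(x)
}

#' Save or load a network as versioned JSON
#'
#' Parameters are stored with explicit shapes and row-major value arrays so
#' a saved model reloads bit-for-bit.
#'
#' @param net a `kmc_network`.
#' @param path file path.
#' @return `write_network`: `path`, invisibly. `read_network`: the network.
#' @export
write_network <- function(net, path) {
  doc <- list(
    format = "kmcloc-network", version = 1L,
    hidden_activation = net$hidden_activation,
    input_size = net$input_size, output_size = net$output_size,
    resolution = net$resolution,
    layers = lapply(net$layers, function(l)
      list(shape = dim(l$W), weights = as.vector(t(l$W)), biases = l$b)),
    conv = if (is.null(net$conv)) NULL else
      lapply(net$conv, function(blk) lapply(blk, function(f)
        list(kernel = as.vector(t(f$kernel)), bias = f$bias)))
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "kmcloc-network"))
    stop("not a kmcloc network file: ", path)
  layers <- lapply(doc$layers, function(l)
    list(W = matrix(l$weights, l$shape[1], l$shape[2], byrow = TRUE),
         b = l$biases))
  net <- new_network(layers, doc$hidden_activation, doc$input_size,
                     doc$output_size, doc$resolution)
  if (!is.null(doc$conv))
    net$conv <- lapply(doc$conv, function(blk) lapply(blk, function(f)
      list(kernel = matrix(f$kernel, 3L, 3L, byrow = TRUE), bias = f$bias)))
  net
}
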