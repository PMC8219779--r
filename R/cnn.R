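#' Single-map 3x3 convolution with zero padding and RELU
#'
#' Applies one 3x3 filter to one map with stride 1 and one-pixel zero
#' padding, adds the filter bias and rectifies, so the output has the same
#' size as the input and is non-negative. This is the per-map primitive of
#' the tree-structured convolution part: each filter reads exactly one map,
#' never a sum across channels.
#'
#' @param map numeric matrix (H x W).
#' @param kernel 3x3 numeric matrix.
#' @param bias scalar.
#' @return H x W numeric matrix, `relu(conv(map) + bias)`.
#' @export
conv2d_single <- function(map, kernel, bias = 0) {
  if (!is.matrix(kernel) || any(dim(kernel) != c(3L, 3L)))
    stop("kernel must be 3x3")
  H <- nrow(map); W <- ncol(map)
  padded <- matrix(0, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- map
  out <- matrix(bias, H, W)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + kernel[dr + 1L, dc + 1L] *
      padded[(1L + dr):(H + dr), (1L + dc):(W + dc)]
  pmax(out, 0)
}

#' 4x4 max-pooling with stride 4
#'
#' Each output cell is the maximum over its disjoint 4x4 window; a 256x256
#' map becomes 64x64.
#'
#' @param map numeric matrix with both sides divisible by 4.
#' @return (H/4) x (W/4) numeric matrix.
#' @export
maxpool <- function(map) {
  H <- nrow(map); W <- ncol(map)
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("map sides must be divisible by 4")
  h <- H %/% 4L; w <- W %/% 4L
  # fold rows then columns: max over each 4-row band, then each 4-col band
  rowmax <- pmax(map[seq(1, H, 4), , drop = FALSE],
                 map[seq(2, H, 4), , drop = FALSE],
                 map[seq(3, H, 4), , drop = FALSE],
                 map[seq(4, H, 4), , drop = FALSE])
  pmax(rowmax[, seq(1, W, 4), drop = FALSE],
       rowmax[, seq(2, W, 4), drop = FALSE],
       rowmax[, seq(3, W, 4), drop = FALSE],
       rowmax[, seq(4, W, 4), drop = FALSE])
}

# Initialize the three per-map convolution blocks: 4 filters on the input
# map, 4 per each of the 4 block-1 maps (16), 4 per each of the 16 block-2
# maps (64); 84 filters, 756 kernel weights and 84 biases in total.
init_conv_part <- function(weight_range = c(-0.2, 0.2),
                           bias_range = c(0, 0.2)) {
  make_filters <- function(n) lapply(seq_len(n), function(i)
    list(kernel = matrix(runif(9, weight_range[1], weight_range[2]), 3L, 3L),
         bias = runif(1, bias_range[1], bias_range[2])))
  list(block1 = make_filters(4L),
       block2 = make_filters(16L),
       block3 = make_filters(64L))
}

#' Forward pass of the tree-structured convolution part
#'
#' Block 1 applies 4 filters to the input map and pools, giving 4 maps of a
#' quarter side; block 2 applies each map's own 4 filters (16 in total) and
#' pools; block 3 likewise (64 filters). With a 256x256 input the trace is
#' 4 maps of 64x64, 16 of 16x16, 64 of 4x4. Filter `f` of block k+1 reads
#' map `ceiling(f / 4)` of block k — the tree structure that keeps the part
#' at 84 filters.
#'
#' @param conv the convolution part (see [build_cnn()]).
#' @param input square numeric matrix with side divisible by 64,
#'   values in `[0, 1]`.
#' @return list of 64 square maps of side `nrow(input) / 64`.
#' @export
forward_conv <- function(conv, input) {
  if (!is.matrix(input) || nrow(input) != ncol(input))
    stop("input must be a square matrix")
  if (nrow(input) %% 64L != 0L)
    stop("input side must be divisible by 64 (three 4x stages)")
  maps <- list(input)
  for (blk in 1:3) {
    nxt <- vector("list", 4L * length(maps))
    for (f in seq_along(conv[[blk]])) {
      src <- maps[[ceiling(f / 4)]]
      filt <- conv[[blk]][[f]]
      nxt[[f]] <- maxpool(conv2d_single(src, filt$kernel, filt$bias))
    }
    maps <- nxt
  }
  maps
}

#' Flatten the 64 final activation maps into one input vector
#'
#' Fixed order: map-major, each map row-major, so 64 maps of 4x4 become a
#' vector of length 1024 feeding the fully-connected head.
#'
#' @param maps list of equally sized square maps.
#' @return numeric vector of length `length(maps) * side^2`.
#' @export
flatten_maps <- function(maps) {
  d <- dim(maps[[1]])
  if (any(!vapply(maps, function(m) identical(dim(m), d), logical(1))))
    stop("all maps must share the same dimensions")
  unlist(lapply(maps, function(m) as.vector(t(m))), use.names = FALSE)
}

#' Build and initialize the tree-structured convolution network
#'
#' Three per-map convolution blocks (84 filters of 3x3, RELU, 4x4
#' max-pooling) followed by a fully-connected head with 49 output nodes.
#' The head has 1 or 2 hidden layers of 49 nodes; its hidden activation is
#' either the bipolar sigmoid or RELU (output nodes are always logistic).
#' With the default 256x256 input the flattened convolution output has
#' length 1024. Initialization ranges match [build_ann()].
#'
#' @param head_widths integer vector of head hidden widths: `49` or
#'   `c(49, 49)`.
#' @param head_activation `"bipolar_sigmoid"` or `"relu"`.
#' @param input_size input side length, divisible by 64 (default 256).
#' @param seed integer seed.
#' @return a `kmc_network` with a `conv` component.
#' @export
build_cnn <- function(head_widths = 49L,
                      head_activation = c("bipolar_sigmoid", "relu"),
                      input_size = 256L, seed = 1L) {
  head_activation <- match.arg(head_activation)
  if (!length(head_widths) %in% 1:2 || any(head_widths < 1))
    stop("'head_widths' must be one or two positive widths")
  if (input_size %% 64L != 0L)
    stop("'input_size' must be divisible by 64")
  set.seed(seed)
  conv <- init_conv_part()
  flat_len <- 64L * (input_size %/% 64L)^2
  widths <- c(flat_len, as.integer(head_widths), 49L)
  layers <- lapply(seq_len(length(widths) - 1L), function(k)
    init_layer(widths[k], widths[k + 1L]))
  net <- new_network(layers, head_activation,
                     input_size = input_size^2, output_size = 49L,
                     resolution = input_size)
  net$conv <- conv
  net
}

#' Forward pass of the full convolution network
#'
#' Convolution part, flatten, then the fully-connected head; outputs lie in
#' (0, 1).
#'
#' @param net a `kmc_network` built by [build_cnn()].
#' @param input row-major flattened normalized image(s): vector of length
#'   `net$input_size` or a matrix with one row per sample.
#' @return output matrix, one row per sample, 49 columns.
#' @export
forward_cnn <- function(net, input) {
  if (is.vector(input)) input <- matrix(input, nrow = 1L)
  if (ncol(input) != net$input_size)
    stop("input length ", ncol(input), " does not match input_size ",
         net$input_size)
  side <- as.integer(sqrt(net$input_size))
  flat <- t(vapply(seq_len(nrow(input)), function(i) {
    img <- matrix(input[i, ], side, side, byrow = TRUE)
    flatten_maps(forward_conv(net$conv, img))
  }, numeric(nrow(net$layers[[1]]$W))))
  forward_ann_head(net, flat)
}

# Head-only forward (the fully-connected part of a CNN).
forward_ann_head <- function(net, flat) {
  y <- flat
  n_layers <- length(net$layers)
  for (k in seq_len(n_layers)) {
    x <- y %*% net$layers[[k]]$W + rep(net$layers[[k]]$b, each = nrow(y))
    kind <- if (k < n_layers) net$hidden_activation else "logistic"
    y <- activation(x, kind)
  }
  y
}
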