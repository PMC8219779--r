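#' Pixel boundaries of the 7x7 localization grid
#'
#' The image is divided into seven horizontal and seven vertical sections,
#' giving 49 boxes per image. For a side of `side` pixels, boundary `k`
#' (k = 0..7) sits at `round(k * side / 7)` (round-half-up); box `(r, c)`
#' covers pixel rows `[b[r], b[r+1])` and the analogous columns, half-open,
#' so the 49 boxes tile the image exactly.
#'
#' @param side image side length in pixels (>= 7).
#' @return integer vector of 8 boundaries from 0 to `side` (0-based).
#' @export
box_boundaries <- function(side) {
  if (side < 7) stop("side must be >= 7 to support a 7x7 grid")
  as.integer(floor(seq(0, 7) * side / 7 + 0.5))
}

#' Convert a binary lesion mask into 49 box targets
#'
#' A box's target is 1 if at least one nonzero mask pixel falls inside it,
#' else 0. Targets are ordered row-major from the top-left box: index 1 is
#' box (row 0, column 0), index 8 is box (row 1, column 0), etc.
#'
#' @param mask square binary matrix (0/1), side >= 7.
#' @return integer vector of length 49 with values in `{0, 1}`.
#' @examples
#' m <- matrix(0L, 49, 49); m[1, 1] <- 1L
#' mask_to_box_targets(m)[1]
#' @export
mask_to_box_targets <- function(mask) {
  if (!is.matrix(mask) || nrow(mask) != ncol(mask))
    stop("mask must be a square matrix")
  side <- nrow(mask)
  b <- box_boundaries(side)
  targets <- integer(49)
  for (r in 0:6) {
    rows <- (b[r + 1] + 1):b[r + 2]
    for (c in 0:6) {
      cols <- (b[c + 1] + 1):b[c + 2]
      targets[r * 7 + c + 1] <- as.integer(any(mask[rows, cols] != 0))
    }
  }
  targets
}

# Row-overlap weight matrix for exact area-average resampling from S source
# pixels to R output pixels: W[j, s] is the fraction of output cell j covered
# by source pixel s; rows sum to 1. Linear in the input by construction.
area_weights <- function(S, R) {
  W <- matrix(0, R, S)
  scale <- S / R
  for (j in seq_len(R)) {
    lo <- (j - 1) * scale
    hi <- j * scale
    s_lo <- floor(lo) + 1
    s_hi <- ceiling(hi)
    for (s in s_lo:min(s_hi, S)) {
      overlap <- min(hi, s) - max(lo, s - 1)
      if (overlap > 0) W[j, s] <- overlap / scale
    }
  }
  W
}

#' Reduce an image to a lower resolution by area averaging
#'
#' Block-mean (area) resampling: each output pixel is the area-weighted mean
#' of the source pixels it covers. Constant inputs map to the same constant
#' and the output range never leaves the input range. Used to reduce the
#' source images to the network input resolutions
#' (20, 30, 40, 60, 80 for the fully-connected models; 256 for the
#' convolution model).
#'
#' @param pixels numeric matrix.
#' @param resolution output side length; must be positive and no larger than
#'   the source sides.
#' @return `resolution` x `resolution` numeric matrix.
#' @export
downsample <- function(pixels, resolution) {
  if (length(resolution) != 1L || resolution <= 0)
    stop("'resolution' must be a positive integer")
  if (resolution > nrow(pixels) || resolution > ncol(pixels))
    stop("'resolution' exceeds the source size")
  Wr <- area_weights(nrow(pixels), resolution)
  Wc <- area_weights(ncol(pixels), resolution)
  Wr %*% pixels %*% t(Wc)
}

#' Normalize gray levels to the unit interval
#'
#' Divides every value by the maximum gray level 255, mapping `[0, 255]`
#' onto `[0, 1]` for use as network input values.
#'
#' @param grid numeric vector or matrix with values in `[0, 255]`.
#' @return same shape, values in `[0, 1]`.
#' @export
normalize_pixels <- function(grid) {
  if (any(grid < 0 | grid > 255))
    stop("pixel values must lie in [0, 255]")
  grid / 255
}

# Row-major flattening of a matrix (row 0 = top scanned left to right).
flatten_rowmajor <- function(m) as.vector(t(m))

#' Build the model input vector for one image
#'
#' Downsamples to `resolution`, divides by 255 and flattens row-major.
#'
#' @param pixels integer matrix in `[0, 255]`.
#' @param resolution target side length.
#' @return numeric vector of length `resolution^2` with values in `[0, 1]`.
#' @export
model_input <- function(pixels, resolution) {
  flatten_rowmajor(normalize_pixels(downsample(pixels, resolution)))
}

#' Preprocess a labeled dataset into model inputs and box targets
#'
#' @param dataset a `labeled_dataset` (see [generate_dataset()]).
#' @param resolution input side length for the model.
#' @return list with `x` (n x resolution^2 matrix of inputs in `[0, 1]`),
#'   `y` (n x 49 matrix of binary box targets), `ids` (character),
#'   `resolution`.
#' @export
prep_dataset <- function(dataset, resolution) {
  if (length(dataset) == 0L) stop("empty dataset")
  x <- t(vapply(dataset, function(im) model_input(im$pixels, resolution),
                numeric(resolution^2)))
  y <- t(vapply(dataset, function(im) mask_to_box_targets(im$mask),
                integer(49)))
  list(x = x, y = y, ids = vapply(dataset, `[[`, character(1), "id"),
       resolution = as.integer(resolution))
}
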