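#' The six overlay colors
#'
#' Fixed RGB values for the named bin colors, ordered from the highest
#' output bin to the lowest: red, brown, yellow, green, blue, cyan.
#'
#' | name  | R   | G   | B   |
#' |-------|-----|-----|-----|
#' | red   | 255 | 0   | 0   |
#' | brown | 139 | 69  | 19  |
#' | yellow| 255 | 255 | 0   |
#' | green | 0   | 200 | 0   |
#' | blue  | 0   | 0   | 255 |
#' | cyan  | 0   | 255 | 255 |
#'
#' @return 6 x 3 numeric matrix in `[0, 1]`, rownames are the color names.
#' @export
overlay_colors <- function() {
  m <- matrix(c(255, 0, 0,
                139, 69, 19,
                255, 255, 0,
                0, 200, 0,
                0, 0, 255,
                0, 255, 255) / 255,
              nrow = 6, byrow = TRUE,
              dimnames = list(c("red", "brown", "yellow", "green",
                                "blue", "cyan"), c("r", "g", "b")))
  m
}

#' Color binning of box outputs above the cutoff
#'
#' The range from the cutoff to 1.0 is divided into 6 equal-width sections;
#' outputs are colored from large to small: red, brown, yellow, green,
#' blue, cyan. Bins are half-open `(low, high]` with the top bin closed at
#' 1.0; a value at or below the cutoff falls in no bin.
#'
#' @param cutoff scalar in (0, 1).
#' @return object of class `color_binning` with `cutoff`, `boundaries`
#'   (7 increasing values from cutoff to 1) and `colors` (highest bin
#'   first).
#' @export
color_binning <- function(cutoff) {
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0 ||
      cutoff >= 1)
    stop("'cutoff' must lie strictly inside (0, 1)")
  structure(list(cutoff = cutoff,
                 boundaries = seq(cutoff, 1, length.out = 7L),
                 colors = rownames(overlay_colors())),
            class = "color_binning")
}

#' Map one box output to its overlay color
#'
#' @param value output value in (0, 1).
#' @param binning a [color_binning()].
#' @return the color name, or `NA` when the value does not exceed the
#'   cutoff (the box is not drawn).
#' @examples
#' b <- color_binning(0.4)
#' bin_output(0.99, b)  # "red"
#' bin_output(0.65, b)  # "green"
#' bin_output(0.39, b)  # NA
#' @export
bin_output <- function(value, binning) {
  stopifnot(inherits(binning, "color_binning"))
  if (value <= binning$cutoff) return(NA_character_)
  width <- (1 - binning$cutoff) / 6
  k <- ceiling((min(value, 1) - binning$cutoff) / width)  # 1 = lowest bin
  binning$colors[7L - min(k, 6L)]
}

# Pixel extent of box (r, c), 0-based grid indices, as 1-based pixel rows
# and columns, matching the half-open grid convention of box_boundaries().
box_extent <- function(side, r, c) {
  b <- box_boundaries(side)
  list(rows = (b[r + 1L] + 1L):b[r + 2L],
       cols = (b[c + 1L] + 1L):b[c + 2L])
}

#' Render predicted-box overlays on an image
#'
#' Draws a 2-pixel colored outline around every grid box whose output
#' exceeds the cutoff, colored by [bin_output()]; the rest of the image is
#' unchanged. Box extents follow the 7x7 grid convention of
#' [box_boundaries()], with outputs in row-major box order.
#'
#' @param pixels square grayscale matrix in `[0, 255]`.
#' @param outputs numeric vector of 49 box outputs in (0, 1).
#' @param cutoff scalar cutoff in (0, 1).
#' @param border outline thickness in pixels.
#' @return H x W x 3 numeric array in `[0, 1]` (an RGB image).
#' @export
render_overlay <- function(pixels, outputs, cutoff, border = 2L) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("'pixels' must be a square matrix")
  if (length(outputs) != 49L) stop("'outputs' must have length 49")
  side <- nrow(pixels)
  gray <- normalize_pixels(pixels)
  img <- array(rep(gray, 3L), dim = c(side, side, 3L))
  binning <- color_binning(cutoff)
  pal <- overlay_colors()
  for (r in 0:6) for (c in 0:6) {
    val <- outputs[r * 7L + c + 1L]
    color <- bin_output(val, binning)
    if (is.na(color)) next
    ext <- box_extent(side, r, c)
    rows <- ext$rows; cols <- ext$cols
    edge_r <- c(utils::head(rows, border), utils::tail(rows, border))
    edge_c <- c(utils::head(cols, border), utils::tail(cols, border))
    for (ch in 1:3) {
      img[edge_r, cols, ch] <- pal[color, ch]
      img[rows, edge_c, ch] <- pal[color, ch]
    }
  }
  img
}

#' Write an overlay to a PNG file
#'
#' @inheritParams render_overlay
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(pixels, outputs, cutoff, path, border = 2L) {
  png::writePNG(render_overlay(pixels, outputs, cutoff, border), path)
  invisible(path)
}
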